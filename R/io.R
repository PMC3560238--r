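# File formats.
#
# The native plain-text network format is a pair of TSV tables sharing a
# path stem: `<stem>.reactions.tsv` (reaction_id, is_internal,
# lower_bound, upper_bound) and `<stem>.stoich.tsv` (metabolite_id,
# reaction_id, coefficient).  Coefficients are serialized as fraction
# strings ("-1", "1/2") so round-trips through text are exact.  SBML
# (Level 2/3, read-only, core + fbc bounds) is supported for
# interoperability with constraint-based model repositories.

# parse a coefficient given as an integer, fraction or decimal string
parse_fraction <- function(s, context = "") {
  s <- trimws(s)
  if (grepl("^[+-]?[0-9]+$", s)) return(as.numeric(s))
  if (grepl("^[+-]?[0-9]+/[0-9]+$", s)) {
    parts <- strsplit(sub("^\\+", "", s), "/", fixed = TRUE)[[1]]
    den <- as.numeric(parts[2])
    if (den == 0) stop(sprintf("zero denominator in coefficient '%s'%s", s, context), call. = FALSE)
    return(as.numeric(parts[1]) / den)
  }
  if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)) {
    return(as.numeric(s))
  }
  stop(sprintf("unparseable coefficient '%s'%s", s, context), call. = FALSE)
}

format_fraction <- function(x) {
  r <- rq_from_num(x)
  ifelse(r$d == 1, sprintf("%.0f", r$n), sprintf("%.0f/%.0f", r$n, r$d))
}

#' Write a network to the TSV pair format
#'
#' @param network a `stoich_network`.
#' @param stem path stem; writes `<stem>.reactions.tsv` and
#'   `<stem>.stoich.tsv`.
#' @return `stem`, invisibly.
#' @export
write_network_tsv <- function(network, stem) {
  stopifnot(inherits(network, "stoich_network"))
  rx <- data.frame(reaction_id = network$reaction_ids,
                   is_internal = as.integer(network$internal),
                   lower_bound = network$lower,
                   upper_bound = network$upper)
  utils::write.table(rx, paste0(stem, ".reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  idx <- which(network$stoich != 0, arr.ind = TRUE)
  st <- data.frame(metabolite_id = network$metabolite_ids[idx[, 1]],
                   reaction_id = network$reaction_ids[idx[, 2]],
                   coefficient = format_fraction(network$stoich[idx]))
  st <- st[order(match(st$reaction_id, network$reaction_ids),
                 match(st$metabolite_id, network$metabolite_ids)), ]
  utils::write.table(st, paste0(stem, ".stoich.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

read_network_tsv <- function(stem) {
  rpath <- paste0(stem, ".reactions.tsv")
  spath <- paste0(stem, ".stoich.tsv")
  for (p in c(rpath, spath)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  rx <- utils::read.delim(rpath, colClasses = "character")
  need <- c("reaction_id", "is_internal", "lower_bound", "upper_bound")
  if (!all(need %in% names(rx))) {
    stop(sprintf("%s must have columns: %s", rpath, paste(need, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(rx$reaction_id)) {
    stop(sprintf("%s: duplicated reaction_id '%s'", rpath,
                 rx$reaction_id[duplicated(rx$reaction_id)][1]), call. = FALSE)
  }
  st <- utils::read.delim(spath, colClasses = "character")
  needs <- c("metabolite_id", "reaction_id", "coefficient")
  if (!all(needs %in% names(st))) {
    stop(sprintf("%s must have columns: %s", spath, paste(needs, collapse = ", ")), call. = FALSE)
  }
  key <- paste(st$metabolite_id, st$reaction_id)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf("%s line %d: duplicate entry for (%s, %s)", spath, i + 1,
                 st$metabolite_id[i], st$reaction_id[i]), call. = FALSE)
  }
  dangling <- setdiff(st$reaction_id, rx$reaction_id)
  if (length(dangling)) {
    stop(sprintf("%s: reaction '%s' is not in the reactions table", spath, dangling[1]),
         call. = FALSE)
  }
  orphan <- setdiff(rx$reaction_id, st$reaction_id)
  if (length(orphan)) {
    stop(sprintf("%s: reaction '%s' has no stoichiometry entries", rpath, orphan[1]),
         call. = FALSE)
  }
  mets <- unique(st$metabolite_id)
  S <- matrix(0, length(mets), nrow(rx),
              dimnames = list(mets, rx$reaction_id))
  for (i in seq_len(nrow(st))) {
    S[st$metabolite_id[i], st$reaction_id[i]] <-
      parse_fraction(st$coefficient[i], sprintf(" (%s line %d)", spath, i + 1))
  }
  stoichiometric_network(S,
                         internal = as.integer(rx$is_internal) == 1L,
                         lower = as.numeric(rx$lower_bound),
                         upper = as.numeric(rx$upper_bound))
}

read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop(sprintf("%s: no species found", path), call. = FALSE)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- tolower(ifelse(is.na(xml2::xml_attr(sp_nodes, "boundaryCondition")),
                                "false", xml2::xml_attr(sp_nodes, "boundaryCondition"))) == "true"
  names(sp_boundary) <- sp_id
  mets <- sp_id[!sp_boundary]

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- as.numeric(xml2::xml_attr(params, "value"))
  names(par_val) <- xml2::xml_attr(params, "id")

  attr_like <- function(node, suffix) {
    at <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", suffix, "$"), names(at))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop(sprintf("%s: no reactions found", path), call. = FALSE)
  rxn_ids <- xml2::xml_attr(rx_nodes, "id")
  n <- length(rxn_ids)
  S <- matrix(0, length(mets), n, dimnames = list(mets, rxn_ids))
  touches_boundary <- logical(n)
  lower <- numeric(n)
  upper <- numeric(n)
  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    rev <- !identical(tolower(xml2::xml_attr(node, "reversible")), "false")
    lb <- ub <- NA_real_
    lb_ref <- attr_like(node, "lowerFluxBound")
    ub_ref <- attr_like(node, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lb <- par_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) ub <- par_val[[ub_ref]]
    kl <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
    if (length(kl)) {
      kid <- xml2::xml_attr(kl, "id")
      kid[is.na(kid)] <- xml2::xml_attr(kl, "name")[is.na(kid)]
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kv[match("LOWER_BOUND", kid)]
      if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kv[match("UPPER_BOUND", kid)]
    }
    lower[j] <- if (!is.na(lb)) lb else if (rev) -1000 else 0
    upper[j] <- if (!is.na(ub)) ub else 1000
    add_side <- function(xpath, sgn) {
      refs <- xml2::xml_find_all(node, xpath)
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        coef_s <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef_s)) 1 else parse_fraction(coef_s, sprintf(" (reaction %s)", rxn_ids[j]))
        if (isTRUE(sp_boundary[[sid]])) {
          touches_boundary[j] <<- TRUE
        } else if (sid %in% mets) {
          S[sid, j] <<- S[sid, j] + sgn * coef
        } else {
          stop(sprintf("%s: reaction '%s' references unknown species '%s'",
                       path, rxn_ids[j], sid), call. = FALSE)
        }
      }
    }
    add_side(".//listOfReactants/speciesReference", -1)
    add_side(".//listOfProducts/speciesReference", +1)
  }
  internal <- !touches_boundary & colSums(S != 0) != 1
  stoichiometric_network(S, internal = internal, lower = lower, upper = upper)
}

#' Read a stoichiometric network from disk
#'
#' @param path for `format = "tsv"`, the path stem of the
#'   `<stem>.reactions.tsv` / `<stem>.stoich.tsv` pair; for
#'   `format = "sbml"`, an SBML file.
#' @param format `"tsv"`, `"sbml"`, or `"auto"` (default: SBML when the
#'   path ends in `.xml`/`.sbml` and exists as a file, else TSV stem).
#' @return a validated `stoich_network`.  SBML species map to
#'   metabolites; boundary-condition species are dropped from the matrix
#'   and reactions touching them — as well as single-entry columns — are
#'   classified exchange; fbc or kinetic-law flux bounds are honored,
#'   with defaults 0/-1000 to 1000 by reversibility.
#' @export
read_network <- function(path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE) && file.exists(path)) {
      "sbml"
    } else "tsv"
  }
  switch(format, tsv = read_network_tsv(path), sbml = read_network_sbml(path))
}

#' Read a flux vector from a two-column TSV
#'
#' @param path TSV file with columns `reaction_id` and `value` (header
#'   optional).
#' @param tolerance sign tolerance for the resulting
#'   [flux_distribution()].
#' @return a [flux_distribution()].
#' @export
read_flux_tsv <- function(path, tolerance = 1e-9) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop(sprintf("%s: expected two tab-separated columns", path), call. = FALSE)
  if (suppressWarnings(is.na(as.numeric(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  vals <- vapply(seq_len(nrow(raw)), function(i) {
    parse_fraction(raw[i, 2], sprintf(" (%s line %d)", path, i))
  }, numeric(1))
  names(vals) <- raw[, 1]
  if (anyDuplicated(names(vals))) {
    stop(sprintf("%s: duplicated reaction '%s'", path,
                 names(vals)[duplicated(names(vals))][1]), call. = FALSE)
  }
  flux_distribution(vals, tolerance = tolerance)
}
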