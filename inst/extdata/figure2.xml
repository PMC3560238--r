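<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_cycle">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M1" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="M2" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="M3" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="M1_ext" compartment="c" boundaryCondition="true" hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_rev" value="-1000" constant="true"/>
      <parameter id="ub_def" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="x1" reversible="true" fast="false" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_def">
        <listOfReactants>
          <speciesReference species="M1_ext" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M1" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="x2" reversible="true" fast="false" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_def">
        <listOfReactants>
          <speciesReference species="M1" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M2" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="x3" reversible="true" fast="false" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_def">
        <listOfReactants>
          <speciesReference species="M2" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M3" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="x4" reversible="true" fast="false" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_def">
        <listOfReactants>
          <speciesReference species="M3" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M1" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
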