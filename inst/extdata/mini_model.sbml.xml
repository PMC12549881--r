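<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini_model" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="metabolite A" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="B" name="metabolite B" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="C" name="metabolite C" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="lb_rev" value="-50" constant="true"/>
      <parameter id="ub_default" value="100" constant="true"/>
      <parameter id="ub_small" value="5" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_A" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="2" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_small">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_C" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
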