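<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy1" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="C" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="P" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="ten" value="10" constant="true"/>
      <parameter id="inf" value="INF" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="G_g4" fbc:label="g4"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_up" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R2" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R3" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_g3"/>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_g1"/>
              <fbc:geneProductRef fbc:geneProduct="G_g4"/>
            </fbc:and>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_biomass" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="inf">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_P" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <listOfReactants>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_biomass" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
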