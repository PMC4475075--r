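<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="linear_chain">
    <listOfCompartments>
      <compartment id="cytosol"/>
      <compartment id="external"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_ext" compartment="external" boundaryCondition="true"/>
      <species id="A" compartment="cytosol"/>
      <species id="B" compartment="cytosol"/>
      <species id="C_ext" compartment="external" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="Tin" reversible="false">
        <listOfReactants><speciesReference species="A_ext"/></listOfReactants>
        <listOfProducts><speciesReference species="A"/></listOfProducts>
      </reaction>
      <reaction id="Conv" reversible="true">
        <listOfReactants><speciesReference species="A"/></listOfReactants>
        <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
      </reaction>
      <reaction id="Tout" reversible="false">
        <listOfReactants><speciesReference species="B"/></listOfReactants>
        <listOfProducts><speciesReference species="C_ext"/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
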