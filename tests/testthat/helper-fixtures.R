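# Synthetic published-model fixtures (built in code; stand-ins for
# user-supplied genome-scale model files, which are not bundled).

cobraJsonFixture <- function(path = tempfile(fileext = ".json")) {
  doc <- list(
    id = "synthetic_mini",
    metabolites = list(
      list(id = "glc_e", name = "glucose", formula = "C6H12O6",
           charge = 0, compartment = "e"),
      list(id = "glc_c", name = "glucose", formula = "C6H12O6",
           charge = 0, compartment = "c"),
      list(id = "bm_e", name = "biomass", formula = "",
           charge = 0, compartment = "e")),
    reactions = list(
      list(id = "EX_glc", name = "glucose exchange",
           metabolites = list(glc_e = -1),
           lower_bound = -1.8, upper_bound = 0, gene_reaction_rule = "",
           objective_coefficient = 0),
      list(id = "GLCt", name = "glucose transport",
           metabolites = list(glc_e = -1, glc_c = 1),
           lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "gT1 and gT2", objective_coefficient = 0),
      list(id = "GROWTH", name = "growth",
           metabolites = list(glc_c = -2, bm_e = 1),
           lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "gX", objective_coefficient = 1),
      list(id = "EX_bm", name = "biomass exchange",
           metabolites = list(bm_e = -1),
           lower_bound = 0, upper_bound = 1000, gene_reaction_rule = "",
           objective_coefficient = 0)),
    genes = list(list(id = "gT1"), list(id = "gT2"), list(id = "gX")))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  path
}

sbmlFixture <- function(path = tempfile(fileext = ".xml")) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="synthetic_mini" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfParameters>
      <parameter id="lb_ex" value="-1.8" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="big" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="M_glc_e" name="glucose" compartment="e" fbc:charge="0"
               fbc:chemicalFormula="C6H12O6" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="M_glc_c" name="glucose" compartment="c" fbc:charge="0"
               fbc:chemicalFormula="C6H12O6" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="M_bm_e" name="biomass" compartment="e" fbc:charge="0"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfGeneProducts xmlns="http://www.sbml.org/sbml/level3/version1/fbc/version2">
      <geneProduct fbc:id="G_gT1" fbc:label="gT1"/>
      <geneProduct fbc:id="G_gT2" fbc:label="gT2"/>
      <geneProduct fbc:id="G_gX" fbc:label="gX"/>
    </listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_EX_glc" name="glucose exchange" reversible="true"
                fast="false" fbc:lowerFluxBound="lb_ex"
                fbc:upperFluxBound="zero">
        <listOfReactants>
          <speciesReference species="M_glc_e" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_GLCt" name="glucose transport" reversible="false"
                fast="false" fbc:lowerFluxBound="zero"
                fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="M_glc_e" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_glc_c" stoichiometry="1"
                            constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_gT1"/>
            <fbc:geneProductRef fbc:geneProduct="G_gT2"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_GROWTH" name="growth" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="M_glc_c" stoichiometry="2"
                            constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_bm_e" stoichiometry="1"
                            constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gX"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_EX_bm" name="biomass exchange" reversible="false"
                fast="false" fbc:lowerFluxBound="zero"
                fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="M_bm_e" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_GROWTH" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>', path)
  path
}
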