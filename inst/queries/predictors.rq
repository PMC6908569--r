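# Retrieve study predictor variables and their levels.
# Reference SPARQL for the traversal implemented by query_predictors();
# the contract is defined by the result set, not by this text.
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX obo:  <http://purl.obolibrary.org/obo/>

SELECT ?variableLabel ?levelLabel
WHERE {
  ?design obo:STATO_0000003 ?variable .        # has independent variable
  ?variable rdfs:label ?variableLabel ;
            obo:STATO_0000004 ?level .         # has factor level
  ?level rdfs:label ?levelLabel .
}
ORDER BY ?variableLabel ?levelLabel
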