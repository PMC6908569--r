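# What is the sample size used to compute the mean?
# Reference SPARQL for the traversal implemented by query_sample_size().
PREFIX rdf:  <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX obo:  <http://purl.obolibrary.org/obo/>

SELECT DISTINCT ?n
WHERE {
  ?measurement rdf:type obo:IAO_0000109 ;     # measurement datum
               obo:STATO_0000008 ?qtype ;     # has quantitation type
               obo:STATO_0000089 ?n .         # computed over sample size
  ?qtype rdf:type obo:STATO_0000401 .         # sample mean
}
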