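# fedsmoke schema vocabulary, version 0.1
# Namespace: http://fedsmoke.org/vocab#
@prefix fs: <http://fedsmoke.org/vocab#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .

fs:Provider a rdfs:Class ; rdfs:comment "A data holder participating in a distributed-analytics execution" .
fs:DataSource a rdfs:Class ; rdfs:comment "One data source technology instance offered by a provider" .
fs:Entity a rdfs:Class ; rdfs:comment "A table, collection or resource type inside a data source" .
fs:Attribute a rdfs:Class ; rdfs:comment "A typed attribute of an entity" .

fs:hasSource a rdf:Property ; rdfs:domain fs:Provider ; rdfs:range fs:DataSource .
fs:hasEntity a rdf:Property ; rdfs:domain fs:DataSource ; rdfs:range fs:Entity .
fs:hasAttribute a rdf:Property ; rdfs:domain fs:Entity ; rdfs:range fs:Attribute .
fs:technology a rdf:Property ; rdfs:domain fs:DataSource ; rdfs:comment "Database-Plugin dispatch IRI" .
fs:datatype a rdf:Property ; rdfs:domain fs:Attribute ; rdfs:comment "Data-Plugin dispatch IRI" .
fs:linksTo a rdf:Property ; rdfs:domain fs:Attribute ; rdfs:range fs:Entity ; rdfs:comment "Foreign-key-like arc to an entity of the same provider" .
fs:name a rdf:Property .
fs:index a rdf:Property ; rdfs:comment "Declaration order, kept so serialization round-trips" .
fs:genMin a rdf:Property .
fs:genMax a rdf:Property .
fs:genChoices a rdf:Property .
fs:genNullProb a rdf:Property .
fs:genLength a rdf:Property .
fs:genWidth a rdf:Property .
fs:genHeight a rdf:Property .

# Atomic data types (each resolved by exactly one Data Plugin)
fs:integer a fs:AtomicType .
fs:double a fs:AtomicType .
fs:string a fs:AtomicType .
fs:boolean a fs:AtomicType .
fs:date a fs:AtomicType .
fs:datetime a fs:AtomicType .
fs:categorical a fs:AtomicType .
fs:uuid a fs:AtomicType .
fs:jpeg a fs:AtomicType .
fs:fhir-Patient a fs:AtomicType .
fs:fhir-Media a fs:AtomicType .
fs:fhir-ImagingStudy a fs:AtomicType .

# Source technologies (each resolved by exactly one Database Plugin)
fs:relational a fs:SourceTechnology .
fs:document a fs:SourceTechnology .
fs:objectstore a fs:SourceTechnology .
fs:fhir a fs:SourceTechnology .
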