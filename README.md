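# metabind

Metadata-driven integration middleware for heterogeneous biological data
sources, in R.

Biological data lives behind wildly different access mechanisms — structured
flat files (GenBank records), XML documents with DTD schemas, web form
endpoints that answer in HTML, relational databases, FTP trees, web
services. Classical mediator systems cope by writing one wrapper per source,
and every new source or interface change means new code. `metabind` takes
the alternative route: all knowledge about a source lives in a **typed
metadata registry** (a generic API ontology), and calls into the source are
**constructed at runtime** from that metadata. Integrating a previously
unknown source is a registration, not a programming task, and swapping the
implementation behind an unchanged interface requires no change anywhere
else (hot swapping).

## The model

The registry classifies, per source *S*:

* **data elements** *E* (Gene, Protein, File, …) with typed attributes and a
  client display hint;
* **user operations** *U(E)* — biologist-level verbs (FetchData,
  SubmitQuery, Read, …). A *simple* operation maps to one generic operation;
  a *complex* one references a state-machine model;
* **generic→concrete mappings** *(g, S) → c*, where *c* is a callable
  descriptor: a live target reference, a method name, and an ordered, typed
  parameter list.

Complex operations are XML state machines whose transitions follow
Event–Condition–Action rules — `ON event IF guard DO action` — where each
action is a generic operation. Execution holds a typed **context**
Γ : name → (type, value); when an action fires, each declared parameter *p*
of the mapped callable is bound by the precedence

1. explicit binding directive,
2. Γ value matching *p* by name **and** type,
3. unique Γ value matching by type (two candidates is an error, not a guess),
4. a registered constructor recipe for *p*'s semantic type,

and the call is made by runtime introspection. Around this core sit four
generic wrappers that turn raw sources into classifiable metadata:
schema-driven flat-file parsing (regex-delimited node hierarchies), DTD
parsing with path enumeration, a declarative web-page API model (multipart
form construction + indexed tag-path extraction from lenient HTML), and a
dynamic SQL statement builder (parameterized; values never enter SQL text).

## Worked example

```r
library(metabind)
mocks <- make_mock_sources(seed = 1)
get_ds_list(mocks$registry)
#> [1] "EBI"      "FTP-mock" "GeneDB"   "BLAST"

ds_operation(mocks$service, "FetchData", "EBI", "Protein",
             parameters = list(query = "pdb:1e12", db = "pdb", format = "raw"))
#> <operation result: ok, payload type 'ProteinRecord'>
#> MOCK-PROTEIN[seed=1]|query=pdb:1e12|db=pdb|format=raw
#> trace:
#>   state event guard                   action outcome
#> 1    s0  step  TRUE webserviceInitialization      ok
#> 2    s1  step  TRUE    webserviceConstructor      ok
#> 3    s2  step  TRUE              Access-Read      ok
```

`FetchData` is registered as a complex operation: the service loads
`FetchData.xml`, whose three actions run in sequence — the initialize and
create steps publish the live service object, then `Access-Read` resolves
to `object1.fetchData("pdb:1e12", "pdb", "raw")` with all three arguments
bound from the context by name and type. The payload is the mock record;
the trace shows exactly which transition fired for which action.

Flat files round-trip through the schema-driven text wrapper:

```r
g <- generate_genbank_flat(3, seed = 7)
tree <- parse_flat_file(genbank_text_schema(), g$text)
identical(tree_extract(tree, "/genbank_db/genbank_entry/ORIGIN"), g$truth$origin)
#> [1] TRUE
```

and the web-page wrapper recovers a planted job id from fixture HTML at the
configured tag path:

```r
apply_filter(parse_response_tags(blast_page_html()),
             "HTML[0]/BODY[3]/DIV[1]/DIV[3]/DIV[7]/TABLE[7]/TR[1]/TD[1]")
#> [1] "Z8PEFDYB016"
```

## Command line

A thin CLI over the same functions ships in `inst/cli/metabind.R`
(`list`, `metadata`, `register`, `parse-text`, `extract-xml`,
`register-xml`, `sm-validate`, `fixtures`, `bench`).
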