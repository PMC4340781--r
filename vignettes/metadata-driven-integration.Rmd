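---
title: "Metadata-driven integration of biological data sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metadata-driven integration of biological data sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabind)
```

## The problem and the approach

Integrating a new biological data source into an analysis system usually
means writing a wrapper: code that knows this source's URL layout, record
format, or API signatures. Wrappers are brittle — every interface change is
a code change — and they do not scale to the rate at which sources appear.
`metabind` replaces per-source wrapper code with **declarative metadata**:
a registry that classifies what a source is (its type), what it contains
(data elements with typed attributes), what a biologist can do with it
(user operations), and how abstract generic operations translate into
concrete calls. At runtime the middleware *constructs* the concrete call
from the metadata and the current execution context; nothing about a
particular source is compiled into the system.

Two consequences drive the design. First, a change in a source's interface
is handled by editing its registry entry, not code. Second, replacing the
implementation behind an unchanged interface needs no action at all: the
component registry holds live targets by reference, so the next dynamically
constructed call simply lands on the new object (hot swapping — shown
directly in the test suite and acceptance script).

## The registry and its guarantees

A registration is atomic: the source entry, its elements, mappings,
operations, and any state-machine model documents are validated as a whole
(cross-references must resolve; `(generic op, source)` and
`(operation, element)` keys must be unique) and either all become visible
or none. Lookup is an indexed map on `(operation, source, element)` rather
than a linear scan — an exact element match beats a wildcard registration,
and two registrations at equal specificity are rejected at registration
time rather than resolved by silent first-match. The registry serializes to
canonical JSON (fixed field order, keyed collections sorted), so
serialize–deserialize–serialize is byte-identical; the store dialect is
JSON rather than an RDF/OWL triple store because the metadata is used as a
typed lookup structure, never reasoned over.

Client display hints (`imp.ui.StringInput` / `getValue` style) are carried
opaquely and returned verbatim to clients; the service never executes them.

## Execution: ECA state machines over a typed context

Complex user operations are XML state machines. The dialect is defined by
this package (a formal DTD ships in `inst/extdata/state-machine.dtd`):
`stateMachine / state / transition / action / bind` elements, transitions
carrying `event`, `guard`, and `to` attributes. Semantics are
Event–Condition–Action: on each event, the current state's outgoing
transitions are examined in declaration order and the first whose event
matches and whose guard is true fires. After each fired action a default
`step` event is auto-emitted, so the purely sequential models that dominate
practice run without an external event source; reactive models can inject
events explicitly.

The guard language is deliberately a small closed algebra — constants,
`exists(key)`, `key == 'literal'`, `matches(key, 'pattern')`, combined with
`and`/`or`/`not` — rather than an embedded expression language: guards must
be safely evaluable against arbitrary contexts and provably side-effect
free (a property test evaluates every guard form and asserts the context is
untouched).

Each state may declare an `onError` target; action failures then divert
there instead of aborting. This is an addition beyond plain ECA semantics,
made because execution over live sources can fail in ways models should be
able to route around; absent a handler the execution error carries the full
trace.

## Parameter binding

The binder fills each declared parameter of a resolved callable by a fixed
precedence: explicit directive, then context value matching by name *and*
type, then a unique context value matching by type, then a registered
constructor recipe for the semantic type. Two same-typed candidates with no
name match raise an ambiguity error — the alternative (take the first) is
silent nondeterminism, which is worse than failing. Construction is limited
to registered recipes (semantic type → function of the context): bounded
and auditable, with every construction logged in the binding report.
Semantic types are strings compared exactly, plus declared widenings; there
is no structural typing.

## The wrappers

**Text.** A text schema is a node hierarchy with regex delimiters (PCRE
dialect, matched case-sensitively). Delimiter text belongs to *neither*
adjacent node: a node's content starts after its start match and ends
before its end match (or before the next sibling's start), and siblings
claim spans left-to-right by earliest match. Consuming delimiters keeps the
coverage invariant clean — leaf spans are non-overlapping and the gaps
between them are exactly the consumed delimiters, which the suite checks
span-by-span. Parsed nodes carry `span_start`/`span_end` offsets so
boundary placement is externally checkable. The ORIGIN strip rule removes
position numbers, whitespace and the record terminator and uppercases the
residue letters, so extracted sequences are directly comparable to ground
truth.

**XML.** The DTD is the primary schema dialect (an XSD subset — nested
element/sequence/choice/attribute — is accepted and labeled as such).
Unsupported constructs (entities, notations, conditional sections, mixed
content beyond `#PCDATA`) fail loudly; silently dropping declarations would
corrupt the classification. Paths are name-only
(`/genbank_db/genbank_entry/origin`), enumeration is depth-first in
declaration order and prefix-closed, recursion is expanded to depth one
with a marker. Documents are *not* validated before extraction — the schema
guides classification, it is not a validator — and namespaced documents are
rejected rather than half-supported.

**Web pages.** A declarative model holds URL, method, headers, user and
fixed form parts, and named response filters. Tag-path ordinals count the
node's position among **all element siblings** of its parent, 0-based; this
is the convention under which both a first-child `BODY[0]` in a minimal
page and a `BODY[3]` preceded by HEAD/SCRIPT/STYLE are consistent, and it
was verified against the lenient (libxml2) HTML parser this package uses. A
per-tag mode (`TD[1]` = second `TD`) is available behind a flag. Multipart
boundaries come from a seeded generator so request bodies are
byte-reproducible in tests. The interactive page-sampling tool this
replaces is approximated by `find_tag_paths()`, which reports the tag paths
of every element holding a target string.

**Relational.** `build_statement()` deparses a statement model into SQL
with `?` placeholders; parameter values never appear in SQL text (the suite
feeds hostile values and scans the emitted SQL). Update/Delete without a
predicate require an explicit allow flag. Execution runs against a small
embedded, in-memory table store that accepts exactly the single-table
subset the builder emits — Select/Insert/Update/Delete with conjunctive
`=`/`<`/`>`/`LIKE` predicates — with primary-key and NOT NULL enforcement.
Keeping the engine inside the package keeps every test offline and the
executed dialect identical to the emitted one.

## Synthetic data: what it does and does not emulate

The generators are pure functions of `(seed, parameters)` and record
ground truth alongside every artifact, so round-trip tests are
self-checking. GenBank-style records default to sequence lengths drawn
uniformly from 120–600 nt — long enough to span multiple 60-residue ORIGIN
lines, short enough to keep hundred-record suites fast — with feature stubs
limited to `source`/`gene`/`CDS` lines. This exercises everything the text
wrapper does (tokens, delimiters, repeatable records, numbered sequence
lines, the `//` terminator) but is *not* release-format GenBank: no
qualifier structure, no multi-line locations, no alternative section types.
Passing tests therefore demonstrate correct schema-driven parsing
mechanics, not coverage of the full flat-file corpus. Likewise the fixture
web page plants its job id at one known tag path; real result pages vary
their structure, which is exactly the variability the declarative model
(not code) is meant to absorb. The naming pair `Initialize`/`Create`
versus `webserviceInitialization`/`webserviceConstructor` occurs in the
field's descriptions of such sequences; the registry treats them as aliases
of one mapping, so either spelling resolves.

## Numerical and procedural choices

* Problem sizes: the suite parses 100-record files, checks 50 random
  callables for invocation equivalence, 25 random HTML trees, 50 random DB
  rows, and runs benchmarks at 1000 repetitions in 20 chunks — sizes chosen
  so the full suite stays in the tens of seconds while each property is
  exercised well past its edge cases.
* Benchmarks report chunked medians (wall clock, microsecond-resolution
  timer) and are asserted only as *trends*: binding time non-decreasing in
  the number of constructed parameters, introspective invocation within a
  3× band across arities 0–3, model-load time non-decreasing in model size
  {1, 5, 20, 50}, and a static call no slower than the full generic path.
  Absolute milliseconds are hardware facts, not package properties.
* The service core is in-process; the JSON-over-HTTP façade (base-R
  sockets, HTTP/1.0, one request per connection) is optional and answers
  byte-identically to the in-process calls — network deployment is a
  deployment detail, not part of the method.
* `execute_model()` bounds fired transitions (`max_steps`, default 10⁴) so
  malformed cyclic models terminate with a diagnostic rather than hang.

## Known limitations

No OWL/DL reasoning or SPARQL; no XPath predicates or namespaces; no
JavaScript or session handling in the web wrapper; single-table SQL only;
no hierarchical or timed states in the state machines. These are scope
decisions, not roadmap gaps: each sits behind a declarative surface that a
richer implementation could replace without touching client code — which
is, after all, the point of the architecture.
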