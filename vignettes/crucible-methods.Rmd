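---
title: "Methods: a declarative, message-driven ETL for scientific metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a declarative, message-driven ETL for scientific metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crucible)
```

## The problem

Scientific metadata aggregation faces two sources of heterogeneity at once:
*access* (REST APIs, file dumps, bundles, listings that must be joined
across several calls) and *shape* (XML, CSV, JSON, each provider with its
own schema). Turning dozens of such sources into one searchable index
requires (i) harvesters that stream arbitrarily large dumps without
materializing them, (ii) a transformation step that curators — not
programmers — can write and test rule by rule, and (iii) an orchestration
layer that scales horizontally and survives worker crashes.

`crucible` implements that architecture as three declarative layers over a
single internal record form, plus a message-routed pipeline:

1. a **document model**: every record, whatever its wire format, becomes an
   ordered hierarchical tree (objects / arrays / scalars);
2. an **ingestion language** compiled to lazy cursors (download, extract,
   partition, join, ingest);
3. the **JSONTL transformation language**: source-path → destination-path
   mapping statements with optional sandboxed apply blocks;
4. a **dispatcher/consumer-container** runtime driven by `(docId, status)`
   messages over persistent queues.

## The document model

Objects are ordered name→tree maps with unique member names; arrays are
ordered lists; scalars are strings, numbers, booleans or null. XML maps by
convention: attributes become `@`-prefixed string members, repeated child
elements collapse into arrays in document order, and an element's own
(trimmed, space-joined) text lands in the member `_$`. Namespace prefixes
stay verbatim (`PDBx:date`), so paths written against the raw XML remain
readable. Values arriving via XML or CSV remain *strings* — transformation
filters compare quoted literals, so `'@num' = '1'` works without a type
system; only native JSON input yields numeric scalars.

Duplicate detection needs a content identity, so each record is hashed:
SHA-256 over a canonical serialization that sorts object members, keeps
array order, and tags scalar types. Equal trees modulo member order hash
equally; `{"a":1}` and `{"a":"1"}` do not.

One representational note: a JSON `{}` and `[]` are both empty containers;
the model distinguishes them (named vs unnamed list) and `jsonlite`
round-trips both faithfully. The synthetic-data generator never emits empty
arrays because records converted from XML cannot contain them (a repeated
member exists only if at least one instance occurred).

## Path matching

Source paths support `$`, quoted/bare names, `..` deep scan, `[*]`, `[n]`
and the equality filter `[?(@.'name' = 'lit')]` (plus `!=`). Three
semantic choices matter and are deliberately uniform:

* **Deep scan** matches *every* occurrence of the named member, shallowest
  first, in document order — standard descendant semantics.
* **Child distributes over arrays**: `$.'a'.'b'` where `a` is an array of
  objects visits each element. This is what makes the same script work
  whether a repeated XML element happened once (object) or many times
  (array).
* **Filters on an array filter its elements**; on a single object they test
  the object itself. Comparison is string-typed (scalars are stringified
  first).

Wildcards and indices on a non-array treat the node as a singleton (`[0]`
and `[*]` select it). This keeps one-element/many-element sources uniform
under the XML collapse rule. The brute-force reference matcher
(`brute_force_match`) implements the same definitions by exhaustive
enumeration and is compared against the engine on 1000 random tree/path
pairs in the acceptance suite.

Destination paths construct branches: `name` overwrites, `name[]` appends a
fresh array element, `name[i]` writes at an index and pads missing slots
with empty objects (`datasetDistributions[2].storedIn` produces two empty
leading elements — the target schema's positional convention).

## JSONTL

Five statement types cover the mapping cases: `let` (constants),
`transform column` (one-to-one / one-to-many, with `assign name from` to
reify entity–attribute–value records), `transform columns` (positional
alignment of several source paths, mandatory apply), `transform union`
(concatenate all matches into a destination array) and `join` (each path's
full match list is handed to the apply block at once — e.g. select the
organism name whose parallel type list says `scientific`, with an
empty-string fallback). All but `join` accept an `if ... then` condition
over source values (`=`, `!=`, `<`, `>`, `<=`, `>=`, `like` with `%`
wildcards, `exists`, `not exists`). `and` binds tighter than `or`; the
ordering operators compare numerically when both sides parse as numbers,
lexically otherwise; a path that matches nothing makes every comparison
false except `not exists`. Keywords are case-insensitive; `//` comments are
stripped outside blocks.

### Apply blocks

Blocks between `{{ }}` are curator-written value manipulations in a small
imperative dialect with Python surface syntax: assignment, string/list
expressions, `a if cond else b`, try/except, `pass`, 0-based indexing,
`re.split`/`re.sub`, list `extend`/`append`/`index`, common string methods
and `len`/`str`/`int`. The interpreter is a closed sandbox — the only names
visible are the statement's bindings (`value`, or `value1..valueN`) and
those builtins; there is no I/O and no import mechanism, because blocks are
untrusted curator input. A block must define `result`; a list-valued
`result` with an array destination spreads one element per value. Both
indented and flat try/except layouts are accepted (copied rules often lose
indentation).

Two alignment decisions were genuinely open and are fixed as follows:
multi-path (`columns`) and EVA name/value pairing align **positionally**
(index *i* of each path's match list forms group *i*; absent values become
empty strings; a name/value count mismatch is an error) — the simplest
semantics consistent with the worked examples; and when a non-array
destination receives several matches, the **first match wins** with a
warning.

### Dates

`toStandardDateTime("yyyy-MM-dd")` is a registered plugin function
(the registry is user-extensible; duplicate registration is an error). The
pattern dialect (`yyyy MM dd HH mm ss`) is tried first; on failure the
value goes through flexible multi-order parsing (month names, reordered
components) via `lubridate`; output is always `YYYY-MM-DDTHH:MM:SS`.
Unparseable input is a transform error — under the default strict mode that
aborts the document; lenient mode (`strict = FALSE`) logs and continues,
which messy sources need.

### Identity scripts

`generate_identity_script()` emits one `transform column` statement per
scalar leaf so that executing the script on the sample reproduces it —
the curator's starting point for a new source. Arrays of scalars map as
`a[*]` → `a[]`; arrays of **objects** use explicit indices (`arr[0].x`)
because per-statement appends would otherwise scatter one element's members
across several destination elements. Nulls are dropped; arrays nested
directly inside arrays are rejected (they cannot arise from the XML/CSV
conversions this targets).

## Ingestion

The ingestion language (`SET` / `DOWNLOAD` / `EXTRACT` / `PARTITION` /
`JOIN` / `INGEST`) compiles to a pipeline of lazy cursors
(`has_next`/`next_record`/`close`, sticky exhaustion). The concrete keyword
grammar is this package's own (the operations and their composition follow
the architecture described above). Key behaviours:

* **Streaming partition.** XML is scanned in 32 KiB chunks for spans of the
  record element; only one record is materialized and DOM-parsed at a time,
  so the first record of a 100,000-record dump is available after a single
  chunk (< 0.5 % of the input; the acceptance suite asserts < 1 %). The
  span scanner tracks nesting of the record tag and self-closing forms; it
  assumes record tags do not appear inside attribute values or CDATA, which
  holds for machine-written metadata dumps. CSV streams one row at a time
  through `read.csv` on an open connection (RFC 4180 quoting, configurable
  delimiter); JSON documents are loaded and iterated via the record path.
* **Joins.** Inner joins on scalar key paths. A static right side is
  drained once into a key index on first use. A right side whose URL still
  contains `${param}` placeholders is *parameterized*: it is fetched on
  demand, the placeholder instantiated with the left record's key, and the
  URL-keyed artifact cache guarantees one fetch per distinct key — the
  acceptance suite asserts exactly one detail fetch per subject. The joined
  record keeps the left tree and nests the right record under a member
  named by the right-side alias, so nothing is silently clobbered and each
  document stays self-contained.
* **Fetchers.** `file://`, plain paths and `http(s)` ship; other transports
  (FTP, rsync, OAI-PMH, databases) are out of scope but plug in behind the
  same `fetch(url) -> local path` contract. Tests use an in-memory
  route-table fetcher implementing the identical contract (with a
  cache-miss log), plus a real `file://` rendering of the same endpoints;
  an in-process HTTP listener was rejected because serving and fetching
  from one single-threaded R process is not reliable. `EXTRACT` understands
  tar bundles and directories (base R `untar`; no external zip tool is
  assumed).

`run_ingestion()` drains the planned cursor, extracts each record's primary
key, and consults the store: unseen `(source, key)` → new; same checksum →
duplicate (skipped); changed checksum → updated. Re-running an unchanged
source therefore ingests nothing — idempotence the pipeline relies on.

## Pipeline orchestration

A run is configured from one four-section file: `database` (store backend),
`mq` (broker parameters), `workflow` (ordered consumer aliases), and
`consumers` (per-alias `class` + output `status` + free options, delivered
verbatim to the plugin's `init`). The route table is derived, not written:
consumer *i*'s output status routes to consumer *i+1*'s queue; the last
status routes to the terminal marker; the start label (`new`) routes to the
first queue. Unknown statuses go to a dead-letter queue — of the possible
behaviours (drop, crash, park), parking preserves evidence without halting
the run.

The reference broker is in-process with lease-based redelivery over a
simulated clock: `take` leases a message, `ack` completes it, an expired
lease requeues it. Consumer containers are independent execution lanes
(one per configured consumer, no shared mutable state between lanes)
multiplexed round-robin; `n` containers mean `n` interleaved replicas.
Crash resilience is tested by killing lanes randomly either before
processing or after the store write but before the status message — both
windows of a real worker death. Exactly-once *effect* comes from
idempotent wrapper writes keyed by `(docId, status)`: redelivered work
overwrites identically, and the conservation property (every ingested id
terminal exactly once: finished ∪ error ∪ dead-letter) holds under chaos.

Because containers are cooperative lanes rather than OS threads, the
scale-invariance and crash tests are deterministic under a seed while still
exercising arbitrary interleavings; what they cannot show is wall-clock
speedup from real parallel hardware, which is a property of the deployment,
not of the routing logic under test.

## Export

Three terminal forms, all ordered by document id so re-export of an
unchanged store is byte-identical: JSON lines (`data` + `_id`/source
envelope), search-engine bulk pairs (action line with
`_id = sourceId:primaryKey`, then the document — two lines per record), and
one sanitized-filename JSON file per document. File export writes JSON;
an ISO-XML dialect would slot in as another export consumer but is out of
scope.

## What the synthetic sources emulate — and what they do not

The generators produce: a three-endpoint project/subject/detail REST source
with its expected join output computed by plain nested loops
(3 × 4 subjects by default, the worked-example scale); PDB-like nested XML
records whose expected transforms are built by direct construction from the
drawn values (never by the engine under test); random trees with
XML-flavoured names for the path-matching oracle; and a 1000-record corpus
for pipeline-scale runs. Sizes were chosen so the full suite runs in a few
minutes on one core: 1000 oracle pairs, 50 identity trees, a
100,000-record streaming dump, 1000 pipeline documents. Passing these shows
the *logic* is right at realistic shapes; it says nothing about provider
quirks (rate limits, malformed encodings, schema drift) or multi-host
throughput.

## Known limitations

* The XML record scanner trusts that record tags do not occur inside
  attribute values, comments or CDATA of *other* elements.
* JSON partitioning loads the document (streaming JSON records would need
  an incremental JSON tokenizer; the formats that actually arrive as huge
  dumps are XML and CSV, which do stream).
* The filter operator set inside path predicates is `=`/`!=` only; the
  condition language carries the ordering operators. Anything else is
  rejected loudly rather than guessed.
* One store/broker per process; the contracts (`put/get/update/find`,
  `put/take/ack`) are the extension points for external backends.
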