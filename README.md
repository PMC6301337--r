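# crucible

Declarative, message-driven ETL for scientific metadata.

Biomedical and earth-science data discovery portals index metadata from
dozens of heterogeneous repositories: REST APIs that must be called and
joined in several stages, multi-gigabyte XML dumps, CSV tables, JSON feeds —
each with its own schema. `crucible` is an R toolkit for that aggregation
problem, aimed at the people who run such indexes and at the curators who
write the per-source rules:

* **Document model** — every source record becomes an ordered hierarchical
  tree (JSON-style objects/arrays/scalars). XML maps by convention:
  attributes become `@`-prefixed members, repeated elements collapse into
  arrays, element text lands in `_$`. Records are checksummed (SHA-256 over
  a canonical, member-order-insensitive serialization) for duplicate
  detection.
* **Ingestion DSL** — declarative harvest scripts (`DOWNLOAD`, `EXTRACT`,
  `PARTITION`, `JOIN`, `INGEST`) compile to lazy streaming cursors: a
  100,000-record XML dump yields its first record after reading well under
  1% of the file, and parameterized REST joins fetch each detail endpoint
  exactly once per distinct key.
* **JSONTL** — a curator-facing transformation language: five statement
  types (`let`, `transform column` with `assign name from`,
  `transform columns`, `transform union`, `join`) mapping source JSONPath
  expressions (child / `..` deep scan / `[*]` / `[n]` /
  `[?(@.'f' = 'v')]` filters) to destination paths (`a.b`, `arr[]`,
  `arr[2]`), with `if ... then` conditions and sandboxed `{{ ... }}` apply
  blocks for arbitrary value manipulation. An identity-script generator
  bootstraps a new source's rules from a sample record.
* **Pipeline** — a dispatcher routes `(docId, status)` messages through a
  route table derived from a four-section YAML config (`database`, `mq`,
  `workflow`, `consumers`); consumer containers host plugin consumers
  (ingestors and enhancers) with create/init/shutdown lifecycles. The
  in-process broker delivers at-least-once with lease-based redelivery, so
  crashed consumers lose nothing, and document sets are invariant to the
  number of containers.
* **Export** — JSON lines, search-engine bulk actions (two lines per
  document), or one JSON file per document.

## A worked example

A record harvested from XML, with an EVA-style name/value block:

```r
library(crucible)

src <- xml_to_tree(paste0(
  "<record><id>GSE100</id>",
  "<metadata><name>species</name><value>rat</value></metadata>",
  "<metadata><name>region</name><value>CA1</value></metadata>",
  "<taxid>10116</taxid><released>Jan 8, 1999</released></record>"))

script <- parse_script('
let "dataRepository.name" = "Demo Repository";
transform column "$.\'metadata\'[*].\'value\'.\'_$\'" to "metadata.value"
  assign name from "$.\'metadata\'[*].\'name\'.\'_$\'";
transform union "$.\'taxid\'.\'_$\'" to "taxonomicInformation[].ID"
  apply {{ result = \'ncbitax:\' + value }};
transform column "$.\'released\'.\'_$\'" to "dataset.dateReleased"
  apply toStandardDateTime();
if "$.\'id\'.\'_$\'" like "%GSE%" then
  let "dataset.storedIn" = "Gene Expression Omnibus";
')

cat(tree_to_json(execute_script(script, src), pretty = TRUE))
```

prints

```json
{
  "dataRepository": {
    "name": "Demo Repository"
  },
  "metadata": {
    "species": "rat",
    "region": "CA1"
  },
  "taxonomicInformation": [
    {
      "ID": "ncbitax:10116"
    }
  ],
  "dataset": {
    "dateReleased": "1999-01-08T00:00:00",
    "storedIn": "Gene Expression Omnibus"
  }
}
```

Reading the output: the `assign name from` statement reified the two
name/value pairs into named members; the union statement wrapped the
taxonomy id into a CURIE; the free-form date was normalized to ISO 8601;
and the conditional constant fired because the accession matched `%GSE%`.

The same machinery scales up: `run_pipeline()` takes a YAML config and a
list of harvest descriptors, ingests each source through its cursor plan
(with checksum-based duplicate detection), drives the documents through the
configured consumer workflow, and leaves them ready for `export_jsonl()` /
`export_bulk()` / `export_files()`. A thin CLI wraps the same functions —
see `system.file("cli", "crucible", package = "crucible")` — with
subcommands `ingest`, `transform`, `test-rule`, `gen-identity`, `run`,
`export` and `fixtures`.

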