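---
title: "How provmark builds, traces and compiles reports"
output: html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(provmark)
```

## Why a programmatic report builder

Analyses in omics work are rarely a single script: they are sequences of
function calls, chosen interactively or through a graphical front-end, with
parameters that never make it into a methods section. The reproducibility of
such work depends on an *audit trail*: a human-readable document that
interleaves narrative with the exact, re-executable code that was run.
Literate-programming documents provide the format; the missing piece is
building them **from code**, so that a pipeline, a package, or a GUI back-end
can grow the document as a side effect of doing the analysis.

provmark is that piece. A report is an object backed by a markdown file on
disk; operations append headings, prose and fenced code chunks; a
wrapper-function factory makes arbitrary functions record their own calls;
and a compiler executes the chunks and renders standalone HTML with captured
outputs, figures, session information, references and a resources table.

## The document model

A report source file is, in order:

1. YAML front matter (`title`, an `author` list with optional email,
   affiliation, affiliation URL, ORCID and personal URL per author, an ISO
   `date` fixed at creation, the output format, the chunk dialect, the
   optional `bibliography` path, and the registered resources);
2. one *global-options* chunk declaring the document-wide execution flags;
3. the body: headings (levels 1–6), verbatim paragraphs, and labelled
   fenced chunks `` ```{r label, key=value, ...} ``.

Two properties are maintained after **every** completed public operation and
are what make the file a trustworthy mirror of the in-memory object:

* *File-mirror*: the file's bytes equal the serialization of the document.
  Each operation validates all its inputs first and then rewrites the file,
  so a failed operation provably leaves the file unchanged.
* *Balanced fences*: even while a chunk is "open" during step-by-step
  construction, the file holds the partial chunk with its closing fence; the
  open state lives only in memory.

Serialization is canonical — fixed front-matter field order, fixed chunk
option order (`eval, echo, include, warning, message, cache, fig.width,
fig.height`), one blank line after every block — which is what makes the
parse→serialize round trip byte-identical, and byte identity in turn is
what the construction-equivalence guarantee (step-by-step versus one-call
chunk building) is tested against.

Chunk headers are *minimal*: only options a caller set explicitly **and**
that differ from the document defaults are written. Resources are stored in
the front matter rather than only in memory so that a report parsed back
from disk compiles with its resources table intact.

## Chunk options and their semantics

| option | default | compile-time meaning |
|---|---|---|
| `eval` | `TRUE` | run the chunk; bindings persist to later chunks |
| `echo` | `TRUE` | show the chunk's code |
| `include` | `TRUE` | show anything of the chunk at all |
| `warning`, `message` | `TRUE` | show captured warnings / messages |
| `cache` | `FALSE` | parsed and re-emitted, currently a no-op |
| `fig_width`, `fig_height` | 7 × 5 in | figure device size |

The visibility rules are exactly: code shown iff `echo ∧ include`; output
shown iff `eval ∧ include`. Two consequences worth spelling out: a chunk
with `eval = FALSE` still *shows* its code (that is the point of disabling
evaluation — documenting a step without re-running it), and a chunk with
`include = FALSE` still *runs* (so it can prepare state for later chunks
invisibly). The full 2×2×2 matrix is verified in the test suite on a
one-statement chunk.

Boolean option values are spelled per dialect (`TRUE`/`FALSE` for the
R-compatible dialect, lowercase otherwise); the dialect tag is a
document-level setting, default `"r"`, which also selects the assignment
operator (`<-`) and the source-file loader statement (`source("...")`).

## Serializing calls: literals, placeholders, raw code

Recording a function call requires turning its arguments into code text.
Three argument classes exist, chosen explicitly because guessing is the
failure mode of provenance systems:

* **Literals** — booleans, integers, doubles, strings, paths, and flat
  unnamed vectors of these. Doubles are serialized as the *shortest* decimal
  text that parses back to the identical IEEE value (tried at 1–17
  significant digits), so re-executing the report is bit-stable. Strings are
  double-quoted with backslash, quote, newline and tab escapes.
* **Placeholders** — an explicit marker (`placeholder("degList")`) that
  renders as a bare variable name. Data-bearing arguments *must* use one;
  the serialized chunk then references the object without embedding its
  value, and re-execution reproduces the call wherever that name is bound to
  equal data. A marker type was chosen over back-tick string munging
  because it is unambiguous and cannot collide with a legitimate string
  value.
* **Raw code** — `raw_code("...")` passes through verbatim, for quoting
  whole expressions.

Arguments are always rendered by keyword (`f(n=3L, flag=TRUE)`), never
positionally, so recorded calls survive signature reordering in later
versions of the traced function. Unsupported values (nested structures,
model objects, environments) raise a serialization error naming the
offending argument — before anything is written to the report.

## The tracing wrapper

`make_traced(target, doc, ...)` returns a function with the target's calling
convention that (1) serializes the invocation, (2) appends one complete
chunk — optionally titled and commented — and (3) performs the call,
returning its value unchanged. Design choices:

* *Record before execution.* If the target fails, the chunk remains: a
  failed attempt is part of the audit trail. The only thing that aborts the
  recording is a serialization error, which happens before any write.
* *Transparency.* For deterministic targets the wrapper is observationally
  identical to the target; this is property-tested over randomized inputs.
* *One call, one chunk.* n invocations append exactly n chunks, counted by
  fence pairs.

This is the pattern a GUI back-end uses: the interface calls the wrapper
where it would have called the plotting or statistics routine, and the
user's point-and-click session accumulates as a compilable report.

## Compilation

`compile_report()` parses the source from disk (never trusting in-memory
state it cannot re-derive), executes chunks **in document order in one
fresh environment** — so a binding created in chunk *k* is visible in chunk
*k+1*, exactly like running the script top to bottom — with the working
directory set to the report's directory, and renders standalone HTML.
Output capture (printed values, warnings, messages, incremental plots) is
done with the `evaluate` engine; prose is rendered with `commonmark`;
figures are replayed onto a PNG device at the chunk's dimensions and
embedded as base64 data URIs by default (a flag writes them beside the
output instead).

Choices made where the design was genuinely open:

* **Session information goes into the output only.** Appending it to the
  source would duplicate it on every recompile; rendering it (interpreter
  version, platform, loaded package versions including this package, and a
  timestamp) as exactly one trailing section keeps compilation idempotent:
  recompiling changes nothing but the timestamp, and the source hash is
  asserted unchanged.
* **References** appear iff a bibliography was set *and* at least one
  `@key` citation occurs in the prose. The BibTeX reader is a small
  brace-aware parser covering the fields the reference list formats
  (author, year, title, venue, DOI); entries are emitted key-sorted and
  unstyled, resolved citations become links, unresolved keys render
  verbatim with a logged warning, and citations with a missing
  bibliography file are a compile error.
* **Resources Availability** appears iff resources were registered: a
  three-column table in insertion order.
* **Error policy** defaults to *halt*: the first failing chunk aborts
  compilation with a condition of class `provmark_compile_error` carrying
  the chunk label, which callers (and the CLI) can handle mechanically.
  *continue* renders the error message in place and keeps going — useful
  for long reports.
* The `cache` option is accepted and round-tripped but not acted on;
  cross-compile caching is out of scope.

## The synthetic RNA-seq demo

`generate_counts()` emulates a small bulk RNA-seq design: three conditions
— two antibody treatments (`DEC`, `E2`) and an untreated control (`UNTR`) —
with two replicates each. Counts are negative-binomial with one dispersion
(default 0.1, a typical bulk-tissue value), gene baseline means
log10-uniform on [0, 3] (1 to 1000 expected counts, spanning the usual
dynamic range), and 10% of genes differentially expressed with an absolute
log2 fold change of 2 in both treatment groups, direction random per gene.
The draw is deterministic for a fixed seed and restores the caller's RNG
state. The demo runs at 500 genes — the machinery under test is the
reporting layer, and its behavior does not depend on the gene count, so the
demo favors the scale at which the whole pipeline builds and compiles in
seconds. (Property checks that need stable fold-change averages use 2000
genes.)

`run_demo_pipeline()` then exercises every module: it writes the counts as
TSV, copies a self-contained helper script into the report tree, and builds
one titled, commented chunk per stage — loading, per-sample diagnostics
with a boxplot, low-count filtering, counts-per-million scaling,
a principal-component projection, per-gene log2 fold changes with a
Welch-style statistic for each treatment against control, and a volcano
plot recorded through `make_traced()` with a placeholder argument — and
compiles the report. The stage math is deliberately elementary (total-count
scaling, base `prcomp`, Welch statistics on two replicates per group): the
demo's role is to exercise the report and tracing machinery on a pipeline
of realistic shape, not to be a differential-expression method, and its
p-values at n = 2 per group should be read accordingly.

What the passing demo shows — and what it does not: it shows that a
multi-stage analysis can be recorded, round-tripped, re-executed and
rendered faithfully; it does not validate statistical performance on real
RNA-seq data, which has empirical mean–dispersion trends, composition
effects and batch structure the generator deliberately omits.

## Numerical and degenerate-input conventions

* Titles accept levels 1–6 only; level and non-empty text are validated
  before any write.
* Chunk labels must be unique; automatic labels are `chunk-<n>` counting
  completed chunks.
* An empty code chunk is legal and equals its one-call counterpart byte
  for byte.
* `filter_low_counts` keeps genes with total count ≥ threshold, so
  kept + removed always equals the input gene count.
* CPM columns sum to 1e6 up to floating tolerance; the PCA drops
  zero-variance genes before centering.
* Parse errors (missing front matter, unclosed or nested fences, unknown
  option keys, malformed values) report the offending line number.

## Known limitations

Inline code spans, child documents and chunk reuse are out of scope, as are
report merging and file locking. PDF output delegates to an external
`pandoc` converter when one is on the PATH; HTML is the first-class format.
The BibTeX reader does not handle `@string` macros or `#` concatenation.
Re-initializing over an existing report errors rather than resuming —
protecting an append-only audit trail — unless `overwrite = TRUE` is given
explicitly.
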