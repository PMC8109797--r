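#' Simulate an RNA-seq count matrix
#'
#' Draws a genes-by-samples matrix of negative-binomial counts emulating a
#' small multi-condition bulk RNA-seq experiment: gene baseline means are
#' log10-uniform over `mean_log_range`, counts share one dispersion, and a
#' `de_fraction` share of genes is differentially expressed — their mean is
#' shifted by `effect_log2fc` (direction random per gene) in every
#' non-control group. The default design is three conditions (two treated,
#' `DEC` and `E2`, and a control, `UNTR`) with two replicates each.
#'
#' @param n_genes number of genes (rows).
#' @param replicates_per_group named integer vector: replicates per
#'   condition. Default `c(DEC = 2, E2 = 2, UNTR = 2)`.
#' @param de_fraction proportion of genes flagged differentially
#'   expressed, in `[0, 1]`. Default 0.10.
#' @param effect_log2fc absolute log2 fold change applied to flagged genes
#'   in non-control groups. Default 2.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#'   Default 0.1.
#' @param mean_log_range range (log10 scale) of gene baseline means.
#'   Default `c(0, 3)`, i.e. means between 1 and 1000.
#' @param control_group condition receiving no effect; default `"UNTR"`,
#'   falling back to the last group when absent.
#' @param seed integer seed; the draw is fully deterministic for a fixed
#'   seed and does not disturb the caller's RNG state.
#' @return a list of class `count_matrix`: `counts` (integer matrix with
#'   gene rownames and `GROUP_rep<i>` colnames), `genes`, `samples` (data
#'   frame with `sample` and `group`), `de_flags` (logical per gene),
#'   `de_sign` (per-gene effect direction), and the generating parameters.
#' @examples
#' cm <- generate_counts(n_genes = 100, seed = 7)
#' dim(cm$counts)
#' @export
generate_counts <- function(n_genes = 500,
                            replicates_per_group = c(DEC = 2, E2 = 2,
                                                     UNTR = 2),
                            de_fraction = 0.10, effect_log2fc = 2,
                            dispersion = 0.1, mean_log_range = c(0, 3),
                            control_group = "UNTR", seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1 ||
      n_genes != as.integer(n_genes))
    stop("generate_counts: n_genes must be a positive integer", call. = FALSE)
  if (!is.numeric(de_fraction) || de_fraction < 0 || de_fraction > 1)
    stop("generate_counts: de_fraction must be in [0, 1]", call. = FALSE)
  if (!is.numeric(effect_log2fc) || effect_log2fc <= 0)
    stop("generate_counts: effect_log2fc must be positive", call. = FALSE)
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("generate_counts: dispersion must be positive", call. = FALSE)
  if (is.null(names(replicates_per_group)) ||
      any(replicates_per_group < 1))
    stop("generate_counts: replicates_per_group must be a named vector of ",
         "positive counts", call. = FALSE)
  if (length(mean_log_range) != 2L || mean_log_range[2] < mean_log_range[1])
    stop("generate_counts: mean_log_range must be an increasing pair",
         call. = FALSE)
  groups <- names(replicates_per_group)
  if (!control_group %in% groups) control_group <- groups[length(groups)]

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  genes <- sprintf("gene_%05d", seq_len(n_genes))
  sample_group <- rep(groups, times = replicates_per_group)
  sample_names <- unlist(lapply(groups, function(g)
    paste0(g, "_rep", seq_len(replicates_per_group[[g]]))))

  base_mu <- 10^stats::runif(n_genes, mean_log_range[1], mean_log_range[2])
  n_de <- round(de_fraction * n_genes)
  de_flags <- rep(FALSE, n_genes)
  if (n_de > 0) de_flags[sample.int(n_genes, n_de)] <- TRUE
  de_sign <- ifelse(stats::runif(n_genes) < 0.5, -1, 1)

  counts <- matrix(0L, nrow = n_genes, ncol = length(sample_names),
                   dimnames = list(genes, sample_names))
  for (j in seq_along(sample_names)) {
    mu <- base_mu
    if (sample_group[j] != control_group) {
      idx <- de_flags
      mu[idx] <- mu[idx] * 2^(de_sign[idx] * effect_log2fc)
    }
    counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }

  structure(list(counts = counts, genes = genes,
                 samples = data.frame(sample = sample_names,
                                      group = sample_group,
                                      stringsAsFactors = FALSE),
                 de_flags = de_flags, de_sign = de_sign,
                 params = list(n_genes = n_genes,
                               replicates_per_group = replicates_per_group,
                               de_fraction = de_fraction,
                               effect_log2fc = effect_log2fc,
                               dispersion = dispersion,
                               mean_log_range = mean_log_range,
                               control_group = control_group,
                               seed = as.integer(seed))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<synthetic count matrix> ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples (", sum(x$de_flags), " DE-flagged)\n",
      sep = "")
  invisible(x)
}

#' Write a count matrix to TSV
#'
#' First column `gene_id`, then one column per sample labelled
#' `GROUP_rep<i>`. Byte-deterministic for a given matrix.
#'
#' @param cm a `count_matrix` from [generate_counts()] (or a bare integer
#'   matrix with dimnames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Run the bundled synthetic RNA-seq demo pipeline
#'
#' End-to-end exercise of the whole package: simulates counts for the
#' three-condition, two-replicate design, writes them to TSV, then builds
#' a report — one titled, commented chunk per stage: loading the counts
#' (through a sourced helper script, so the report stays self-contained),
#' per-sample diagnostics with a boxplot, low-count filtering, scaling to
#' counts per million, a principal-component projection, per-gene
#' two-group comparisons (log2 fold change plus a Welch-style statistic)
#' of each treatment against the control, and a volcano plot recorded via
#' [make_traced()] — and compiles it to standalone HTML. The same stage
#' computations are also performed in-process, so the returned object
#' carries the numeric results the report displays.
#'
#' The stage math is deliberately elementary (total-count scaling, base
#' `prcomp`, Welch statistics): the demo's job is to exercise the
#' reporting and tracing machinery on a realistic pipeline shape, not to
#' be a differential-expression method.
#'
#' @param output_dir directory for the report, counts TSV and helper
#'   script (created if needed).
#' @param n_genes number of simulated genes; default 500.
#' @param seed simulation seed; the report source is byte-identical across
#'   runs with the same seed (same-day date field).
#' @param filter_threshold genes with total count below this are dropped;
#'   default 10.
#' @param compile logical; compile to HTML (default `TRUE`).
#' @return a list with `doc`, `report_path`, `html_path` (`NULL` when not
#'   compiled), `counts` (the `count_matrix`), `n_kept`/`n_removed` from
#'   the filter, `deg` (named list of per-contrast tables), and
#'   `n_figures` counted from the compiled HTML.
#' @examples
#' \donttest{
#' res <- run_demo_pipeline(file.path(tempdir(), "demo"), n_genes = 200,
#'                          seed = 7)
#' res$n_kept
#' }
#' @export
run_demo_pipeline <- function(output_dir, n_genes = 500, seed = 1,
                              filter_threshold = 10, compile = TRUE) {
  dir.create(file.path(output_dir, "script"), recursive = TRUE,
             showWarnings = FALSE)
  cm <- generate_counts(n_genes = n_genes, seed = seed)
  write_counts_tsv(cm, file.path(output_dir, "counts.tsv"))
  helper_src <- system.file("extdata", "demo_functions.R",
                            package = "provmark", mustWork = TRUE)
  helper <- file.path(output_dir, "script", "demo_functions.R")
  file.copy(helper_src, helper, overwrite = TRUE)

  doc <- create_report(
    file.path(output_dir, "rnaseq_report"),
    title = "RNA-seq Analysis Report",
    authors = "provmark demo",
    overwrite = TRUE)
  add_resource(doc, "synthetic counts",
               "negative-binomial simulated count matrix (3 conditions x 2 replicates)",
               "counts.tsv")
  add_text(doc, paste0(
    "This report was generated programmatically; every analysis stage ",
    "below is a re-executable code chunk. Simulation seed: ", seed, "."))

  add_complete_chunk(doc,
    code = 'geneCounts <- read_counts("counts.tsv")',
    source_files = "script/demo_functions.R",
    title = "Loading Counts Data", level = 1,
    comment = "Raw counts are loaded from the TSV written by the simulator.",
    label = "load-counts")

  add_complete_chunk(doc,
    code = list("sample_summary(geneCounts)",
                "diagnostic_boxplot(geneCounts)"),
    title = "Per-sample Diagnostics", level = 1,
    comment = "Library sizes, detected genes and count distributions.",
    label = "diagnostics")

  add_complete_chunk(doc,
    code = list(
      sprintf("filtered <- filter_low_counts(geneCounts, %d)",
              as.integer(filter_threshold)),
      "nrow(filtered)"),
    title = "Filtering Low-count Genes", level = 1,
    comment = sprintf(
      "Genes with a total count below %d across all samples are removed.",
      as.integer(filter_threshold)),
    label = "filter")

  add_complete_chunk(doc,
    code = list("cpm <- cpm_scale(filtered)",
                "round(colSums(cpm))"),
    title = "Normalization (Counts per Million)", level = 1,
    comment = "Total-count scaling; every column sums to one million.",
    label = "cpm")

  add_complete_chunk(doc,
    code = list("pca <- pca_project(log2(cpm + 1))",
                'grp <- sub("_rep[0-9]+$", "", colnames(cpm))',
                "pca_plot(pca, grp)"),
    title = "Principal Component Projection", level = 1,
    comment = "Samples projected on the first two components of log2 CPM.",
    label = "pca")

  add_complete_chunk(doc,
    code = list(
      'degList <- list(DECvsUNTR = de_table(cpm, grep("^DEC_", colnames(cpm)), grep("^UNTR_", colnames(cpm))), E2vsUNTR = de_table(cpm, grep("^E2_", colnames(cpm)), grep("^UNTR_", colnames(cpm))))',
      "deg <- degList$DECvsUNTR",
      "head(deg[order(deg$p_value), ], 10)"),
    title = "Differential Expression", level = 1,
    comment = paste(
      "Per-gene mean log2 fold change and a Welch-style two-sample",
      "statistic for each treatment against the control."),
    label = "de")

  # in-process replica of the stages, for return values and for the traced
  # volcano call (the wrapper needs the real data at call time)
  stage_env <- new.env(parent = globalenv())
  sys.source(helper, envir = stage_env)
  filtered <- stage_env$filter_low_counts(cm$counts, filter_threshold)
  cpm <- stage_env$cpm_scale(filtered)
  deg <- list(
    DECvsUNTR = stage_env$de_table(cpm, grep("^DEC_", colnames(cpm)),
                                   grep("^UNTR_", colnames(cpm))),
    E2vsUNTR = stage_env$de_table(cpm, grep("^E2_", colnames(cpm)),
                                  grep("^UNTR_", colnames(cpm))))

  traced_volcano <- make_traced(
    stage_env$volcano_plot, doc, name = "volcano_plot",
    title = "Volcano Plot", level = 1,
    comment = paste("Effect size against significance for the DEC contrast;",
                    "the call below was recorded automatically by the",
                    "tracing wrapper."),
    placeholder_names = list(deg = "deg"))
  grDevices::png(file.path(tempdir(), "provmark-demo-volcano.png"))
  tryCatch(traced_volcano(deg = deg$DECvsUNTR),
           finally = grDevices::dev.off())

  html_path <- NULL
  n_figures <- 0L
  if (compile) {
    html_path <- compile_report(doc)
    html <- readLines(html_path, warn = FALSE)
    n_figures <- sum(lengths(regmatches(html, gregexpr("<img ", html,
                                                       fixed = TRUE))))
  }
  list(doc = doc, report_path = doc$path, html_path = html_path,
       counts = cm, n_kept = nrow(filtered),
       n_removed = nrow(cm$counts) - nrow(filtered), deg = deg,
       n_figures = n_figures)
}
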