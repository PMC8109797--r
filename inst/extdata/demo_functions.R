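# Self-contained analysis helpers for the synthetic RNA-seq demo report.
# Sourced by the report's first code chunk; every later chunk calls into
# these, so the compiled document re-runs the whole pipeline from the TSV.

read_counts <- function(path) {
  as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
}

sample_summary <- function(counts) {
  data.frame(sample = colnames(counts),
             library_size = colSums(counts),
             genes_detected = colSums(counts > 0),
             median_count = apply(counts, 2, median))
}

diagnostic_boxplot <- function(counts) {
  boxplot(log2(counts + 1), las = 2, cex.axis = 0.8,
          ylab = "log2(count + 1)", main = "Per-sample count distributions")
}

filter_low_counts <- function(counts, threshold) {
  counts[rowSums(counts) >= threshold, , drop = FALSE]
}

cpm_scale <- function(counts) {
  sweep(counts, 2, colSums(counts), "/") * 1e6
}

pca_project <- function(logexpr) {
  # samples as observations; constant genes carry no information
  keep <- apply(logexpr, 1, stats::sd) > 0
  prcomp(t(logexpr[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
}

pca_plot <- function(pca, groups) {
  pct <- round(100 * pca$sdev[1:2]^2 / sum(pca$sdev^2), 1)
  plot(pca$x[, 1], pca$x[, 2], pch = 19, col = as.integer(factor(groups)),
       xlab = paste0("PC1 (", pct[1], "%)"),
       ylab = paste0("PC2 (", pct[2], "%)"),
       main = "Principal component projection")
  text(pca$x[, 1], pca$x[, 2], labels = rownames(pca$x), pos = 3)
  legend("topright", legend = levels(factor(groups)), pch = 19,
         col = seq_along(levels(factor(groups))))
}

# per-gene two-group comparison: mean log2 fold change on log2(CPM + 1)
# plus a Welch two-sample statistic and its p-value
de_table <- function(cpm, treated_cols, control_cols) {
  le <- log2(cpm + 1)
  a <- le[, treated_cols, drop = FALSE]
  b <- le[, control_cols, drop = FALSE]
  log2fc <- rowMeans(a) - rowMeans(b)
  va <- apply(a, 1, var)
  vb <- apply(b, 1, var)
  se <- sqrt(va / ncol(a) + vb / ncol(b))
  tstat <- ifelse(se > 0, log2fc / se, 0)
  df <- ifelse(se > 0,
               (va / ncol(a) + vb / ncol(b))^2 /
                 ((va / ncol(a))^2 / (ncol(a) - 1) +
                  (vb / ncol(b))^2 / (ncol(b) - 1)),
               1)
  pval <- 2 * pt(-abs(tstat), df = pmax(df, 1))
  data.frame(gene = rownames(cpm), log2FC = log2fc, t = tstat,
             p_value = pval, row.names = NULL)
}

volcano_plot <- function(deg, alpha = 0.05) {
  neglogp <- -log10(pmax(deg$p_value, 1e-300))
  sig <- deg$p_value < alpha & abs(deg$log2FC) >= 1
  plot(deg$log2FC, neglogp, pch = 16, cex = 0.4,
       col = ifelse(sig, "red", "grey40"),
       xlab = "log2 fold change", ylab = "-log10 p-value",
       main = "Volcano plot")
  abline(v = c(-1, 1), h = -log10(alpha), lty = 2, col = "grey60")
  invisible(sum(sig))
}
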