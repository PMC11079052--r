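# Independent oracles used across tests. These are deliberately written
# from first principles (explicit sums, naive loops) so they do not share
# code paths with the implementation.

# squared Pearson correlation from the closed-form sums
pearson_r2 <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  (num / den)^2
}

# naive substring Hamming scan (both strands optional)
naive_probe_scan <- function(seq, probe, max_mm, both_strands = FALSE) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  count_one <- function(p) {
    s <- strsplit(seq, "")[[1]]
    pp <- strsplit(p, "")[[1]]
    total <- 0L
    for (i in seq_len(length(s) - length(pp) + 1L)) {
      mm <- sum(s[i:(i + length(pp) - 1L)] != pp)
      if (mm <= max_mm) total <- total + 1L
    }
    total
  }
  n <- count_one(probe)
  if (both_strands) n <- n + count_one(revcomp(probe))
  n
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# Jaccard overlap of two pixel sets (logical masks)
jaccard <- function(a, b) sum(a & b) / sum(a | b)

# per-nucleus Jaccard between a label mask and ground truth, matching each
# ground-truth nucleus to its best-overlapping predicted label
per_nucleus_jaccard <- function(pred, truth) {
  ids <- setdiff(sort(unique(as.vector(truth))), 0L)
  vapply(ids, function(id) {
    t_mask <- truth == id
    labs <- pred[t_mask]
    labs <- labs[labs > 0]
    if (length(labs) == 0) return(0)
    best <- as.integer(names(which.max(table(labs))))
    jaccard(pred == best, t_mask)
  }, numeric(1))
}
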