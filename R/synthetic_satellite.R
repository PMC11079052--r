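#' Nucleotide sequence with a CpG methylation mask
#'
#' A plain ACGT string plus the set of methylated CpG cytosines. Methylation
#' is modeled on the forward-strand C of each CpG only (the assays emulated
#' here cannot distinguish hemimethylation). Positions are 1-based within R;
#' the BED-like export ([write_methylation_bed()]) converts to 0-based
#' half-open intervals.
#'
#' @param seq nucleotide string over A/C/G/T (case-insensitive).
#' @param methylated integer vector of 1-based positions of methylated CpG
#'   cytosines; every position `p` must satisfy `seq[p] == "C"` and
#'   `seq[p+1] == "G"`.
#' @return an object of class `methylated_seq`.
#' @export
methylated_seq <- function(seq, methylated = integer(0)) {
  chars <- check_acgt(seq_to_chars(seq))
  methylated <- sort(unique(as.integer(methylated)))
  if (length(methylated) > 0L) {
    stop_if_not(all(methylated >= 1L & methylated < length(chars)),
                "methylated positions must lie within the sequence")
    ok <- chars[methylated] == "C" & chars[methylated + 1L] == "G"
    stop_if_not(all(ok), "position %d is not a CpG cytosine",
                if (any(!ok)) methylated[which(!ok)[1L]] else 0L)
  }
  structure(list(seq = paste(chars, collapse = ""), methylated = methylated),
            class = "methylated_seq")
}

#' @export
print.methylated_seq <- function(x, ...) {
  n <- nchar(x$seq)
  cpg <- cpg_positions(x$seq)
  cat(sprintf("methylated_seq: %d nt, %d CpG sites, %d methylated\n",
              n, length(cpg), length(x$methylated)))
  invisible(x)
}

#' 1-based positions of CpG cytosines in a sequence
#' @param seq nucleotide string (or `methylated_seq`).
#' @return integer vector of positions `p` with `seq[p:p+1] == "CG"`.
#' @export
cpg_positions <- function(seq) {
  if (inherits(seq, "methylated_seq")) seq <- seq$seq
  chars <- seq_to_chars(seq)
  n <- length(chars)
  if (n < 2L) return(integer(0))
  which(chars[-n] == "C" & chars[-1L] == "G")
}

#' Simulate a tandem satellite repeat array with CpG methylation
#'
#' Concatenates `n_copies` of `unit_seq`, applies independent per-base
#' substitutions at `substitution_rate` (to one of the three other bases),
#' then methylates each CpG cytosine of the mutated array independently with
#' probability `cpg_methylation_prob`. Emulates the long, heavily methylated
#' pericentromeric satellite arrays that underlie chromocenters.
#'
#' @param unit_seq repeat unit over A/C/G/T.
#' @param n_copies number of tandem copies (>= 1).
#' @param substitution_rate per-base substitution probability in `[0, 1]`.
#' @param cpg_methylation_prob per-CpG methylation probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a [methylated_seq()] of length `n_copies * nchar(unit_seq)`.
#' @examples
#' arr <- simulate_satellite_array("ACGTAAATTT", 5, 0, 1, seed = 1)
#' arr$methylated
#' @export
simulate_satellite_array <- function(unit_seq, n_copies,
                                     substitution_rate = 0,
                                     cpg_methylation_prob = 0,
                                     seed = 1L) {
  unit <- check_acgt(seq_to_chars(unit_seq), "unit_seq")
  stop_if_not(is_count(n_copies, 1), "n_copies must be >= 1")
  stop_if_not(is_number(substitution_rate, 0) && substitution_rate <= 1,
              "substitution_rate must be in [0, 1]")
  stop_if_not(is_number(cpg_methylation_prob, 0) && cpg_methylation_prob <= 1,
              "cpg_methylation_prob must be in [0, 1]")
  withr::with_seed(seed, {
    chars <- rep(unit, n_copies)
    if (substitution_rate > 0) {
      hit <- which(runif(length(chars)) < substitution_rate)
      bases <- c("A", "C", "G", "T")
      for (i in hit)
        chars[i] <- sample(setdiff(bases, chars[i]), 1L)
    }
    seq <- paste(chars, collapse = "")
    cpg <- cpg_positions(seq)
    meth <- if (length(cpg) > 0L && cpg_methylation_prob > 0)
      cpg[rbinom(length(cpg), 1L, cpg_methylation_prob) == 1L]
    else integer(0)
    methylated_seq(seq, meth)
  })
}

#' Write / read a CpG methylation mask as a BED-like table
#'
#' Three tab-separated columns (name, start, end), 0-based half-open, one row
#' per methylated CpG covering the dinucleotide.
#'
#' @param ms a `methylated_seq`.
#' @param path file path.
#' @param name sequence name for column 1.
#' @param seq the sequence the mask belongs to (for reading).
#' @return `write_methylation_bed()` the path invisibly;
#'   `read_methylation_bed()` a `methylated_seq`.
#' @export
write_methylation_bed <- function(ms, path, name = "seq") {
  stop_if_not(inherits(ms, "methylated_seq"), "ms must be a methylated_seq")
  d <- data.frame(name = name, start = ms$methylated - 1L,
                  end = ms$methylated + 1L)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation_bed
#' @export
read_methylation_bed <- function(path, seq) {
  if (file.size(path) == 0) return(methylated_seq(seq))
  d <- utils::read.table(path, sep = "\t",
                         col.names = c("name", "start", "end"))
  methylated_seq(seq, d$start + 1L)
}
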