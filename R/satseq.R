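#' Restriction enzymes with CpG-methylation sensitivity
#'
#' A minimal enzyme model for methylation-sensitive digest simulation: an
#' IUPAC recognition site, the cut offset within the site (top strand,
#' 0-based between-base), and whether cutting is blocked by CpG methylation
#' anywhere in the recognition window. The built-ins are the two
#' sensitive/insensitive pairs used to probe satellite methylation:
#' HpyCH4IV (`ACGT`, blocked) / ApoI (`RAATTY`, not blocked) for mouse major
#' satellite, and the isoschizomers HpaII (`CCGG`, blocked) / MspI (`CCGG`,
#' not blocked) for red deer satellite I.
#'
#' @param name enzyme name.
#' @param iupac_site recognition site (IUPAC codes allowed).
#' @param cut_offset cut position within the site, in `[0, nchar(site)]`.
#' @param blocked_by_cpg_methylation is cutting blocked when any CpG in the
#'   matched window is methylated?
#' @return an object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, iupac_site, cut_offset,
                               blocked_by_cpg_methylation) {
  site <- seq_to_chars(iupac_site)
  stop_if_not(length(site) > 0, "site must be non-empty")
  bad <- which(!site %in% names(IUPAC_CODES))
  stop_if_not(length(bad) == 0, "invalid IUPAC code '%s' in site",
              if (length(bad)) site[bad[1L]] else "")
  stop_if_not(is_count(cut_offset, 0) && cut_offset <= length(site),
              "cut_offset must be in [0, site length]")
  structure(list(name = name, iupac_site = paste(site, collapse = ""),
                 cut_offset = as.integer(cut_offset),
                 blocked_by_cpg_methylation = isTRUE(blocked_by_cpg_methylation)),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @return `restriction_enzymes()` returns the named list of built-ins.
#' @export
restriction_enzymes <- function() {
  list(
    HpyCH4IV = restriction_enzyme("HpyCH4IV", "ACGT", 1L, TRUE),
    ApoI = restriction_enzyme("ApoI", "RAATTY", 1L, FALSE),
    HpaII = restriction_enzyme("HpaII", "CCGG", 1L, TRUE),
    MspI = restriction_enzyme("MspI", "CCGG", 1L, FALSE)
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("%s: %s, cut offset %d, %s by CpG methylation\n",
              x$name, x$iupac_site, x$cut_offset,
              if (x$blocked_by_cpg_methylation) "blocked" else "not blocked"))
  invisible(x)
}

resolve_enzyme <- function(enzyme) {
  if (is.character(enzyme)) {
    built <- restriction_enzymes()
    stop_if_not(enzyme %in% names(built), "unknown enzyme '%s'", enzyme)
    built[[enzyme]]
  } else {
    stop_if_not(inherits(enzyme, "restriction_enzyme"),
                "enzyme must be a restriction_enzyme or a built-in name")
    enzyme
  }
}

as_methylated_seq <- function(x) {
  if (inherits(x, "methylated_seq")) x else methylated_seq(x)
}

#' GC content of a nucleotide sequence
#'
#' @param seq nucleotide string (or `methylated_seq` / Biostrings object).
#' @param skip_ambiguous drop non-ACGT characters instead of erroring; the
#'   percentage is then computed over the ACGT characters only.
#' @return percentage, `100 * (#G + #C) / length`.
#' @examples
#' gc_content("GCGC")  # 100
#' @export
gc_content <- function(seq, skip_ambiguous = FALSE) {
  if (inherits(seq, "methylated_seq")) seq <- seq$seq
  chars <- seq_to_chars(seq)
  stop_if_not(length(chars) > 0, "sequence must be non-empty")
  if (skip_ambiguous) {
    chars <- chars[chars %in% c("A", "C", "G", "T")]
    stop_if_not(length(chars) > 0, "no unambiguous bases in sequence")
  } else {
    check_acgt(chars)
  }
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Find methylation-aware restriction sites
#'
#' Scans the top strand for IUPAC matches of the enzyme's recognition site
#' (the built-in sites are palindromic, so one strand suffices). For
#' methylation-blocked enzymes a match is suppressed when any methylated CpG
#' cytosine lies within the matched window. Cut positions are 0-based
#' between-base indices (`match start + cut_offset`).
#'
#' @param ms a [methylated_seq()] (or a plain string, treated as
#'   unmethylated).
#' @param enzyme a [restriction_enzyme()] or a built-in name such as
#'   `"HpaII"`.
#' @return sorted integer vector of cut positions.
#' @examples
#' find_sites("TACGTA", "HpyCH4IV")                    # cut at 2
#' find_sites(methylated_seq("TACGTA", 3), "HpyCH4IV") # blocked
#' @export
find_sites <- function(ms, enzyme) {
  ms <- as_methylated_seq(ms)
  enzyme <- resolve_enzyme(enzyme)
  s <- seq_to_chars(ms$seq)
  site <- seq_to_chars(enzyme$iupac_site)
  m <- length(site)
  n <- length(s)
  if (n < m) return(integer(0))
  hits <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    allowed <- IUPAC_CODES[[site[j]]]
    hits <- hits & s[j:(n - m + j)] %in% allowed
  }
  starts <- which(hits)
  if (enzyme$blocked_by_cpg_methylation && length(ms$methylated) > 0L &&
      length(starts) > 0L) {
    methC <- logical(n)
    methC[ms$methylated] <- TRUE
    cs <- cumsum(methC)
    # any methylated C within [start, start + m - 1]?
    n_meth <- cs[starts + m - 1L] - c(0, cs)[starts]
    starts <- starts[n_meth == 0L]
  }
  sort(as.integer(starts - 1L + enzyme$cut_offset))
}

#' Digest a (possibly methylated) linear sequence
#'
#' @inheritParams find_sites
#' @return an object of class `digest_result`: `cut_positions` (0-based
#'   between-base) and `fragment_lengths` (nt, summing to the sequence
#'   length; linear topology).
#' @examples
#' digest("AAACGTAAA", "HpyCH4IV")$fragment_lengths  # 3, 6
#' @export
digest <- function(ms, enzyme) {
  ms <- as_methylated_seq(ms)
  len <- nchar(ms$seq)
  cuts <- find_sites(ms, enzyme)
  cuts <- cuts[cuts > 0L & cuts < len]
  frags <- diff(c(0L, cuts, len))
  structure(list(cut_positions = cuts, fragment_lengths = as.integer(frags)),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("digest: %d cuts, %d fragments (%s nt)\n",
              length(x$cut_positions), length(x$fragment_lengths),
              paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

#' Count probe matches by sliding-window Hamming comparison
#'
#' Slides the probe along the sequence and counts windows with at most
#' `max_mismatches` mismatches; overlapping matches are counted. With
#' `both_strands = TRUE` the reverse complement of the probe is scanned too,
#' with positions still reported on the given strand.
#'
#' @param seq subject sequence (string or `methylated_seq`).
#' @param probe probe sequence (ACGT).
#' @param max_mismatches allowed Hamming mismatches per window.
#' @param both_strands also scan the reverse complement of the probe.
#' @return list with `count` and `positions` (data frame `start` (1-based),
#'   `strand`, `mismatches`).
#' @export
count_probe_matches <- function(seq, probe, max_mismatches = 0L,
                                both_strands = FALSE) {
  if (inherits(seq, "methylated_seq")) seq <- seq$seq
  s <- seq_to_chars(seq)
  p <- check_acgt(seq_to_chars(probe), "probe")
  stop_if_not(length(p) <= length(s),
              "probe longer than the subject sequence")
  stop_if_not(is_count(max_mismatches, 0), "max_mismatches must be >= 0")

  scan_one <- function(p, strand) {
    m <- length(p); n <- length(s)
    mism <- integer(n - m + 1L)
    for (j in seq_len(m))
      mism <- mism + (s[j:(n - m + j)] != p[j])
    idx <- which(mism <= max_mismatches)
    if (length(idx) == 0L) return(NULL)
    data.frame(start = idx, strand = strand, mismatches = mism[idx])
  }

  res <- scan_one(p, "+")
  if (both_strands) {
    rc <- seq_to_chars(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(paste(p, collapse = "")))))
    res <- rbind(res, scan_one(rc, "-"))
  }
  if (is.null(res))
    res <- data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0))
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  list(count = nrow(res), positions = res)
}

#' Bundled satellite probe sequences
#'
#' Returns the packaged probe FASTA as a `DNAStringSet`: the red deer
#' satellite I Southern probe (725 nt, GC-rich), the mouse major satellite
#' Southern probe (804 nt; a cloned amplicon spanning three repeat-unit
#' copies plus vector-derived flanks), and the 23-nt mouse major satellite
#' FISH oligo.
#'
#' @return a [Biostrings::DNAStringSet] of the three probes.
#' @export
satellite_probes <- function() {
  path <- system.file("extdata", "satellite_probes.fa", package = "chromofoci",
                      mustWork = TRUE)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub(" .*", "", names(x))
  x
}
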