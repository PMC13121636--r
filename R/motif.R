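#' Classify center-A pentamers against the DRACH consensus
#'
#' The consensus is D-R-A-C-H with D = A/G/T, R = A/G, a fixed central A, a
#' fixed C at position 4 and H = A/C/T (U in RNA notation maps to T in
#' reference space). Mismatches are counted at positions 1, 2, 4 and 5:
#' zero mismatches is `DRACH`; a single mismatch at position 5 is
#' `DRACN_1mm` (still DRAC-conform in the first four bases); a single
#' mismatch at position 1, 2 or 4 is `nonDRACN_1mm`; two or more mismatches
#' is `multi_mm`. The `DRAC` set used to restrict downstream analyses is
#' `DRACH` plus `DRACN_1mm` (24 pentamers).
#'
#' @param pentamer character vector of 5-mers with an A at the center.
#' @param strict error (rather than return `NA`) on malformed pentamers.
#' @return character vector of classes
#'   (`DRACH`, `DRACN_1mm`, `nonDRACN_1mm`, `multi_mm`).
#' @export
classify_motif <- function(pentamer, strict = TRUE) {
  pentamer <- toupper(pentamer)
  bad <- nchar(pentamer) != 5L | grepl("[^ACGT]", pentamer) |
    substr(pentamer, 3, 3) != "A"
  if (any(bad)) {
    if (strict)
      stop_glorid("pentamers must be 5-mers over ACGT with a central A",
                  "glorid_input_error")
  }
  p1 <- substr(pentamer, 1, 1); p2 <- substr(pentamer, 2, 2)
  p4 <- substr(pentamer, 4, 4); p5 <- substr(pentamer, 5, 5)
  mm_first4 <- (!p1 %in% c("A", "G", "T")) + (!p2 %in% c("A", "G")) +
    (p4 != "C")
  mm5 <- !p5 %in% c("A", "C", "T")
  total <- mm_first4 + mm5
  out <- ifelse(total == 0L, "DRACH",
                ifelse(total >= 2L, "multi_mm",
                       ifelse(mm5, "DRACN_1mm", "nonDRACN_1mm")))
  out[bad] <- NA_character_
  out
}

#' Partition counts of all 256 center-A pentamers by motif class
#'
#' @return named integer vector over the four classes (sums to 256).
#' @export
motif_partition_counts <- function() {
  b <- c("A", "C", "G", "T")
  all_p <- apply(expand.grid(b, b, "A", b, b, stringsAsFactors = FALSE),
                 1, paste, collapse = "")
  cls <- classify_motif(all_p)
  counts <- table(factor(cls, levels = c("DRACH", "DRACN_1mm",
                                         "nonDRACN_1mm", "multi_mm")))
  setNames(as.integer(counts), names(counts))
}

#' Summaries of site motif usage and per-class methylation
#'
#' Returns per-pentamer frequencies (summing to 1), the top-`k` pentamers
#' (ties broken by count descending, then pentamer lexicographic), per-class
#' methylation level quartiles, and a position frequency matrix over the
#' five motif positions.
#'
#' @param sites annotated sites (needs `pentamer`, `motif_class`, `level`).
#' @param top_k size of the top-pentamer table.
#' @return list with `frequencies`, `top`, `class_levels`, `pfm`.
#' @export
motif_summary <- function(sites, top_k = 15L) {
  if (nrow(sites) == 0L) {
    empty <- data.frame(pentamer = character(0), n = integer(0),
                        frequency = numeric(0))
    return(list(frequencies = empty, top = empty,
                class_levels = data.frame(), pfm = matrix(numeric(0), 4, 0)))
  }
  tab <- as.data.frame(table(pentamer = sites$pentamer),
                       stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  tab$frequency <- tab$n / sum(tab$n)
  tab <- tab[order(-tab$n, tab$pentamer), , drop = FALSE]
  rownames(tab) <- NULL

  cl <- split(sites$level, factor(sites$motif_class,
                                  levels = c("DRACH", "DRACN_1mm",
                                             "nonDRACN_1mm", "multi_mm")))
  class_levels <- do.call(rbind, lapply(names(cl), function(k) {
    x <- cl[[k]]
    if (length(x) == 0L) return(NULL)
    data.frame(motif_class = k, n = length(x), median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))

  mat <- do.call(rbind, strsplit(sites$pentamer, "", fixed = TRUE))
  pfm <- sapply(seq_len(5), function(j)
    tabulate(factor(mat[, j], levels = c("A", "C", "G", "T")), 4) /
      nrow(mat))
  dimnames(pfm) <- list(c("A", "C", "G", "T"), paste0("pos", 1:5))

  list(frequencies = tab, top = head(tab, top_k),
       class_levels = class_levels, pfm = pfm)
}

#' Restrict sites to the DRAC consensus
#'
#' Keeps sites whose pentamer conforms to DRAC in the first four bases
#' (classes `DRACH` and `DRACN_1mm`); these are the high-confidence m6A
#' calls used by every downstream stage.
#'
#' @param sites classified sites (needs `motif_class`).
#' @return the DRAC-conform subset.
#' @export
restrict_to_drac <- function(sites) {
  assert_columns(sites, "motif_class", "site table")
  out <- sites[sites$motif_class %in% c("DRACH", "DRACN_1mm"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
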