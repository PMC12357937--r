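# Transposable-element signatures in newly gained introns: target-site
# duplications (TSD), terminal inverted repeats (TIR), internal tandem
# repeats, and interspersed genomic copies.
#
# DNA transposon insertion leaves a short direct repeat of the target site
# flanking the element (staggered-cut repair) and the element itself often
# carries reverse-complementary terminal arms.  An intron born by transposon
# insertion can therefore be recognized by these marks plus the presence of
# similar sequence at multiple unrelated genomic loci.  Note the splice
# dinucleotides gt..ag may lie *inside* the repeats, so the detectors allow
# repeats to straddle the exon/intron junctions.

seq_chars <- function(x) strsplit(tolower(as.character(x)), "", fixed = TRUE)[[1L]]

#' Detect target-site duplication candidates around an intron
#'
#' Searches for exact direct repeats (length `min_len`..`max_len`) with one
#' occurrence overlapping or lying within `window` nt of the 5' intron
#' boundary and another at the 3' boundary.  Repeats may straddle the
#' exon/intron junction (default) or be restricted to the exonic flanks
#' (`strict_exonic = TRUE`).
#'
#' @param flank5,intron,flank3 Nucleotide strings: upstream exonic flank,
#'   intron, downstream exonic flank.
#' @param min_len,max_len Repeat length range searched (default 3..10).
#' @param window Maximum distance (nt) between a repeat occurrence and its
#'   boundary; 0 means overlapping or abutting only.
#' @param strict_exonic If `TRUE`, occurrences must lie entirely in the
#'   flanks.
#' @return Data frame of candidates sorted by descending length then 5'
#'   proximity: `length`, `seq`, `start5`, `end5`, `start3`, `end3`
#'   (0-based half-open, relative to the intron start, so negative
#'   coordinates are exonic 5' flank), `dist5`, `dist3`.  Zero rows when
#'   nothing qualifies.
#' @export
detect_tsd <- function(flank5, intron, flank3, min_len = 3, max_len = 10,
                       window = 10, strict_exonic = FALSE) {
  if (!nchar(flank5) || !nchar(flank3)) stop("flanks must be non-empty")
  if (nchar(intron) < 4) stop("intron must be at least 4 nt")
  full <- tolower(paste0(flank5, intron, flank3))
  n5 <- nchar(flank5); ni <- nchar(intron)
  b5 <- n5               # 0-based position of first intron base
  b3 <- n5 + ni          # 0-based position of first 3' flank base
  n <- nchar(full)
  rows <- list()
  for (L in seq(min_len, max_len)) {
    if (L > n) break
    starts <- 0:(n - L)                       # 0-based
    ## distance from occurrence span [s, s+L) to a boundary point b
    dist_to <- function(s, b) pmax(0L, pmax(s - b, b - (s + L)))
    d5 <- dist_to(starts, b5); d3 <- dist_to(starts, b3)
    s5 <- starts[d5 <= window]
    s3 <- starts[d3 <= window]
    if (strict_exonic) {
      s5 <- s5[s5 + L <= b5]
      s3 <- s3[s3 >= b3]
    }
    if (!length(s5) || !length(s3)) next
    for (a in s5) for (b in s3) {
      if (a == b) next
      wa <- substr(full, a + 1L, a + L)
      wb <- substr(full, b + 1L, b + L)
      if (wa != wb) next
      rows[[length(rows) + 1L]] <- data.frame(
        length = L, seq = wa,
        start5 = a - b5, end5 = a + L - b5,
        start3 = b - b5, end3 = b + L - b5,
        dist5 = dist_to(a, b5), dist3 = dist_to(b, b3),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(length = integer(), seq = character(),
                      start5 = integer(), end5 = integer(),
                      start3 = integer(), end3 = integer(),
                      dist5 = integer(), dist3 = integer()))
  out <- do.call(rbind, rows)
  out[order(-out$length, out$dist5, out$start5), , drop = FALSE]
}

#' Detect a terminal inverted repeat in an element
#'
#' Considers prefix/suffix arm pairs from `min_arm` outward whose left arm
#' matches the reverse complement of the right arm with identity at least
#' `1 - max_mismatch`, and among those reports the arm maximizing
#' `matches - (1 - max_mismatch) * arm_length` — so an exact-armed element
#' is reported at its true arm length with identity 1 rather than padded
#' out to the identity floor.  Reports the first and last trinucleotides of
#' the element (DNA transposon TIRs often start `tgt...` and end `...aca`).
#'
#' @param element Nucleotide string (the putative transposable element).
#' @param min_arm Minimum arm length (default 8).
#' @param max_mismatch Maximum mismatch fraction within an arm (default 0.2).
#' @return A list (`arm_length`, `identity`, `left_arm`, `right_arm`,
#'   `left_start3`, `right_end3`) or `NULL` when no arm of the minimum
#'   length qualifies.
#' @export
detect_tir <- function(element, min_arm = 8, max_mismatch = 0.2) {
  element <- tolower(as.character(element))
  n <- nchar(element)
  if (n < 2 * min_arm) stop("element shorter than twice the minimum arm")
  ch <- seq_chars(element)
  rc <- seq_chars(reverse_complement(element))  # rc[i] = complement of ch[n-i+1]
  matches <- cumsum(ch == rc)                   # prefix vs rev-comp suffix
  thr <- 1 - max_mismatch
  best <- NULL; best_excess <- -Inf
  for (a in seq(min_arm, n %/% 2L)) {
    if (matches[a] / a < thr) next
    excess <- matches[a] - thr * a
    if (excess > best_excess) { best_excess <- excess; best <- a }
  }
  if (is.null(best)) return(NULL)
  list(arm_length = best,
       identity = matches[best] / best,
       left_arm = substr(element, 1L, best),
       right_arm = substr(element, n - best + 1L, n),
       left_start3 = substr(element, 1L, 3L),
       right_end3 = substr(element, n - 2L, n))
}

## Per-k best window: the segment of the shifted-match indicator vector m
## maximizing (matches - min_match * length) subject to length >= k (so at
## least two full copies fit), found exactly via prefix sums.  A positive
## score implies the segment's match fraction exceeds min_match.
## Returns NULL or list(score, excess, span_start, span_len, fraction).
tandem_best_window <- function(m, k, min_match) {
  n <- length(m)
  if (n < k) return(NULL)                       # need >= 2 copies
  s <- cumsum(c(0, m - min_match))              # s[j+1] = sum over m[1..j]
  best <- NULL
  run_min <- Inf; run_arg <- 0L
  for (j in k:n) {
    i <- j - k + 1L                             # window [i, j] has length k
    if (s[i] < run_min) { run_min <- s[i]; run_arg <- i }
    excess <- s[j + 1L] - run_min
    if (is.null(best) || excess > best$excess) {
      len <- j - run_arg + 1L
      matches <- excess + min_match * len
      best <- list(excess = excess, score = matches,
                   span_start = run_arg, span_len = len,
                   fraction = matches / len)
    }
  }
  if (is.null(best) || best$excess <= 0) return(NULL)
  best
}

#' Detect the tandem-repeat period of a sequence
#'
#' For each candidate unit length `k`, positions `i` with
#' `seq[i] == seq[i + k]` form a match indicator, and the segment maximizing
#' `matches - min_match * length` (with at least two copies spanned) is
#' found exactly; a positive score means the segment's match fraction
#' exceeds `min_match`.  The reported unit is the `k` with the highest
#' segment score, ties going to the smallest `k` — so a 37-nt array is
#' reported as unit 37, not 74, and a homopolymer collapses to the smallest
#' admissible unit (flagged as low complexity).
#'
#' @param seq Nucleotide string.
#' @param min_unit,max_unit Unit length range searched (default 5..100).
#' @param min_match Minimum shifted-match fraction over the window
#'   (default 0.8).
#' @return A list (`unit_length`, `copies`, `span_start`, `span_end`
#'   0-based half-open, `match_fraction`, `low_complexity`, `unit_seq`) or
#'   `NULL` when no unit qualifies.
#' @export
tandem_period <- function(seq, min_unit = 5, max_unit = 100,
                          min_match = 0.8) {
  seq <- tolower(as.character(seq))
  n <- nchar(seq)
  if (n < 2 * min_unit) stop("sequence shorter than twice the minimum unit")
  ch <- seq_chars(seq)
  best <- NULL
  for (k in seq(min_unit, min(max_unit, n %/% 2L))) {
    m <- as.integer(ch[seq_len(n - k)] == ch[(k + 1L):n])
    w <- tandem_best_window(m, k, min_match)
    if (is.null(w)) next
    if (is.null(best) || w$excess > best$w$excess)
      best <- list(k = k, w = w)
  }
  if (is.null(best)) return(NULL)
  k <- best$k; w <- best$w
  span_start <- w$span_start - 1L               # 0-based
  span_len <- w$span_len + k                    # window + one unit = full span
  unit_seq <- substr(seq, span_start + 1L, span_start + k)
  list(unit_length = k,
       copies = span_len / k,
       span_start = span_start,
       span_end = span_start + span_len,
       match_fraction = w$fraction,
       low_complexity = length(unique(seq_chars(unit_seq))) == 1L,
       unit_seq = unit_seq)
}

#' Seed-and-extend search for interspersed genomic copies of a query
#'
#' Finds contig regions similar to the query by exact k-mer seeding, chains
#' seeds lying on (nearly) the same diagonal, and scores each chained
#' region's ungapped identity against the query.  Hits passing the coverage
#' and identity thresholds are returned; the query's own locus can be
#' excluded by its coordinates.
#'
#' @param query Nucleotide string.
#' @param contigs Named character vector of contig sequences.
#' @param k Seed length (default 13).
#' @param min_coverage Minimum fraction of the query covered (default 0.5).
#' @param min_identity Minimum ungapped identity over the covered span
#'   (default 0.8).
#' @param gap_budget Maximum diagonal drift when chaining seeds (default 5).
#' @param exclude Optional own locus `list(contig_id =, start =, end =)`
#'   (0-based half-open) whose overlapping hits are dropped.
#' @return Data frame `contig_id`, `start`, `end` (0-based half-open on the
#'   contig), `query_coverage`, `identity`, sorted by descending coverage.
#' @export
scan_interspersed <- function(query, contigs, k = 13, min_coverage = 0.5,
                              min_identity = 0.8, gap_budget = 5,
                              exclude = NULL) {
  query <- tolower(as.character(query))
  nq <- nchar(query)
  if (nq < k) stop("query shorter than the seed length")
  qch <- seq_chars(query)
  qmers <- substring(query, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
  qpos <- split(seq_along(qmers), qmers)        # kmer -> query starts (1-based)
  hits <- list()
  for (cid in names(contigs)) {
    ctg <- tolower(contigs[[cid]])
    nc <- nchar(ctg)
    if (nc < k) next
    cmers <- substring(ctg, seq_len(nc - k + 1L), seq_len(nc - k + 1L) + k - 1L)
    idx <- which(cmers %in% names(qpos))
    if (!length(idx)) next
    seeds <- do.call(rbind, lapply(idx, function(i)
      cbind(q = qpos[[cmers[i]]], c = i)))
    diag <- seeds[, "c"] - seeds[, "q"]
    o <- order(diag, seeds[, "q"])
    seeds <- seeds[o, , drop = FALSE]; diag <- diag[o]
    ## group seeds into chains of near-constant diagonal
    grp <- cumsum(c(1L, abs(diff(diag)) > gap_budget))
    cch <- seq_chars(ctg)
    for (g in unique(grp)) {
      sg <- seeds[grp == g, , drop = FALSE]
      qs <- min(sg[, "q"]); qe <- max(sg[, "q"]) + k - 1L
      d <- as.integer(round(stats::median(sg[, "c"] - sg[, "q"])))
      cs <- qs + d; ce <- qe + d
      if (cs < 1L || ce > nc) { cs <- max(1L, cs); ce <- min(nc, ce); qs <- cs - d; qe <- ce - d }
      span <- qe - qs + 1L
      ident <- mean(qch[qs:qe] == cch[(qs + d):(qe + d)])
      cov <- span / nq
      if (cov < min_coverage || ident < min_identity) next
      if (!is.null(exclude) && identical(cid, exclude$contig_id) &&
          cs - 1L < exclude$end && ce > exclude$start) next
      hits[[length(hits) + 1L]] <- data.frame(
        contig_id = cid, start = cs - 1L, end = ce,
        query_coverage = cov, identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), query_coverage = numeric(),
                      identity = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(-out$query_coverage, -out$identity), , drop = FALSE]
  ## one hit per locus: drop hits overlapping a better hit on the same contig
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    prior <- out[keep & out$contig_id == out$contig_id[i], , drop = FALSE]
    keep[i] <- !any(prior$start < out$end[i] & prior$end > out$start[i])
  }
  out <- out[keep, , drop = FALSE]
  out[order(-out$query_coverage, -out$identity, out$contig_id), , drop = FALSE]
}

#' Classify an intron as a putative transposable element
#'
#' Runs all detectors on an intron and its exonic flanks: target-site
#' duplication, terminal inverted repeat (on the sequence between the top
#' TSD copies when one is found, otherwise on the whole intron), internal
#' tandem repeat, and interspersed genomic copies.  The intron is called a
#' putative TE when it matches at least `min_loci` distinct other loci, the
#' operational version of "homologous to multiple loci".
#'
#' @param flank5,intron,flank3 Nucleotide strings.
#' @param contigs Named character vector of genome contigs to scan.
#' @param min_loci Minimum number of distinct interspersed loci (default 3).
#' @param exclude Own locus passed to [scan_interspersed()].
#' @param ... Further arguments to the individual detectors are taken at
#'   their defaults.
#' @return List of class `"te_classification"`: `is_putative_te`, `n_loci`,
#'   and `evidence` (list with `tsd`, `tir`, `tandem`, `interspersed`).
#' @export
classify_te <- function(flank5, intron, flank3, contigs, min_loci = 3,
                        exclude = NULL, ...) {
  tsd <- detect_tsd(flank5, intron, flank3)
  element <- tolower(intron)
  if (nrow(tsd)) {
    top <- tsd[1L, ]
    ## element between the two repeat copies, intron-relative coordinates
    es <- max(0L, top$end5); ee <- min(nchar(intron), top$start3)
    if (ee - es >= 16L) element <- substr(tolower(intron), es + 1L, ee)
  }
  tir <- if (nchar(element) >= 16L) detect_tir(element) else NULL
  tandem <- if (nchar(intron) >= 10L) tandem_period(intron) else NULL
  inter <- scan_interspersed(intron, contigs, exclude = exclude)
  n_loci <- nrow(unique(inter[, c("contig_id", "start")]))
  structure(list(is_putative_te = n_loci >= min_loci,
                 n_loci = n_loci,
                 evidence = list(tsd = tsd, tir = tir, tandem = tandem,
                                 interspersed = inter)),
            class = "te_classification")
}

#' @export
print.te_classification <- function(x, ...) {
  cat(sprintf("putative transposable element: %s (%d interspersed locus/loci)\n",
              if (x$is_putative_te) "yes" else "no", x$n_loci))
  ev <- x$evidence
  if (nrow(ev$tsd))
    cat(sprintf("  TSD: %d nt '%s'\n", ev$tsd$length[1L], ev$tsd$seq[1L]))
  if (!is.null(ev$tir))
    cat(sprintf("  TIR: %d nt arms, identity %.2f (%s...%s)\n",
                ev$tir$arm_length, ev$tir$identity, ev$tir$left_start3,
                ev$tir$right_end3))
  if (!is.null(ev$tandem))
    cat(sprintf("  tandem: %d nt unit x %.1f copies\n",
                ev$tandem$unit_length, ev$tandem$copies))
  invisible(x)
}
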