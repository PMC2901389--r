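#' Per-position information vector of a frequency matrix
#'
#' `I(i) = sum_B f(i,B) * ln(4 f(i,B))` (nats, with `0 ln 0 := 0`): 0 at a
#' uniform position, `ln 4` at a fully conserved one. Also derives the
#' matrix core — the 5 consecutive positions maximising `sum I(i)`,
#' leftmost on ties — which is attached to the returned vector.
#'
#' @param pwm A [position_frequency_matrix()] with length >= 5.
#' @return Numeric vector `I` with attribute `core_start`.
#' @export
information_vector <- function(pwm) {
  stopifnot(inherits(pwm, "position_frequency_matrix"))
  L <- ncol(pwm$freq)
  if (L < 5)
    stop("matrix shorter than 5 positions: core undefined", call. = FALSE)
  I <- info_values(pwm$freq)
  core <- core_window(I, 5L)
  attr(I, "core_start") <- core
  I
}

# I(i) per column; 0*log(0) treated as 0.
info_values <- function(freq) {
  w <- freq * log(4 * freq)
  w[freq == 0] <- 0
  colSums(w)
}

# Leftmost start of the `len`-wide window maximising the information sum.
core_window <- function(I, len) {
  L <- length(I)
  if (L <= len) return(1L)
  sums <- vapply(seq_len(L - len + 1), function(s) sum(I[s:(s + len - 1)]), 0)
  which.max(sums)  # first maximum = leftmost tie
}

# Precomputed scoring profile: information weights, per-position min/max
# contributions, and core column indices (full width when L < 5).
pwm_profile <- function(pwm) {
  f <- pwm$freq
  L <- ncol(f)
  I <- info_values(f)
  w <- sweep(f, 2, I, "*")             # I(i) * f(i, B)
  wmin <- I * apply(f, 2, min)
  wmax <- I * apply(f, 2, max)
  core <- if (L >= 5) core_window(I, 5L) + 0:4 else seq_len(L)
  if (sum(wmax) - sum(wmin) <= 0 ||
      sum(wmax[core]) - sum(wmin[core]) <= 0)
    stop(sprintf("degenerate matrix '%s': all informative range is zero",
                 pwm$id), call. = FALSE)
  list(w = w, wmin = wmin, wmax = wmax, core = core, L = L,
       min_all = sum(wmin), max_all = sum(wmax),
       min_core = sum(wmin[core]), max_core = sum(wmax[core]))
}

#' MATCH matrix and core similarity scores for one window
#'
#' `Current = sum_i I(i) f(i, b_i)`; the matrix similarity score is
#' `(Current - Min) / (Max - Min)` where Min/Max use the per-position
#' minimum/maximum frequencies; the core similarity score is computed
#' identically over the 5-position core (the whole matrix when it is
#' shorter than 5). A matrix whose informative range is zero (all
#' positions uniform) is a degeneracy error.
#'
#' @param pwm A [position_frequency_matrix()].
#' @param window Character scalar over `A,C,G,T`, of the matrix length.
#' @return List with `mss` and `css`, both in `[0, 1]`.
#' @export
match_scores <- function(pwm, window) {
  prof <- pwm_profile(pwm)
  b <- match(strsplit(toupper(window), "")[[1]], c("A", "C", "G", "T"))
  if (length(b) != prof$L)
    stop(sprintf("window length %d != matrix length %d", length(b), prof$L),
         call. = FALSE)
  if (anyNA(b))
    stop("window contains a non-ACGT character (skip such windows upstream)",
         call. = FALSE)
  contrib <- prof$w[cbind(b, seq_len(prof$L))]
  list(mss = (sum(contrib) - prof$min_all) / (prof$max_all - prof$min_all),
       css = (sum(contrib[prof$core]) - prof$min_core) /
             (prof$max_core - prof$min_core))
}

# reverse complement for plain character strings (gaps preserved)
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

# Score every offset of `codes` (integer base codes, NA for non-ACGT)
# against a profile; returns numeric vectors mss/css with NA at skipped
# (non-ACGT-containing) windows.
scan_codes <- function(prof, codes) {
  L <- prof$L
  n_off <- length(codes) - L + 1
  if (n_off < 1) return(list(mss = numeric(), css = numeric()))
  cur <- numeric(n_off); cur_core <- numeric(n_off)
  ok <- rep(TRUE, n_off)
  for (i in seq_len(L)) {
    ci <- codes[i:(i + n_off - 1)]
    ok <- ok & !is.na(ci)
    contrib <- prof$w[cbind(ci, i)]
    contrib[is.na(contrib)] <- 0
    cur <- cur + contrib
    if (i %in% prof$core) cur_core <- cur_core + contrib
  }
  mss <- (cur - prof$min_all) / (prof$max_all - prof$min_all)
  css <- (cur_core - prof$min_core) / (prof$max_core - prof$min_core)
  mss[!ok] <- NA_real_; css[!ok] <- NA_real_
  list(mss = mss, css = css)
}

#' Scan a sequence for matrix matches
#'
#' Scores every window of the matrix length against the matrix (and, when
#' `both_strands`, against the reverse complement, reported on strand `-`
#' with the offset mapped back to the forward sequence) and returns the
#' windows reaching both the matrix and core similarity cutoffs. Windows
#' containing any non-ACGT character are skipped.
#'
#' @param pwm A [position_frequency_matrix()].
#' @param seq Character scalar (DNA).
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @param matrix_cutoff,core_cutoff Optional overrides of the matrix's own
#'   cutoffs.
#' @return Data.frame with columns `offset` (0-based, forward
#'   coordinates), `strand`, `mss`, `css`.
#' @export
scan_sequence <- function(pwm, seq, both_strands = TRUE,
                          matrix_cutoff = NULL, core_cutoff = NULL) {
  prof <- pwm_profile(pwm)
  mcut <- if (is.null(matrix_cutoff)) pwm$matrix_cutoff else matrix_cutoff
  ccut <- if (is.null(core_cutoff)) pwm$core_cutoff else core_cutoff
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < prof$L)
    return(data.frame(offset = integer(), strand = character(),
                      mss = numeric(), css = numeric()))
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  fwd <- scan_codes(prof, codes)
  hit_f <- which(!is.na(fwd$mss) & fwd$mss >= mcut & fwd$css >= ccut)
  out <- data.frame(offset = hit_f - 1L, strand = rep("+", length(hit_f)),
                    mss = fwd$mss[hit_f], css = fwd$css[hit_f],
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc_codes <- rev(5L - codes)   # A<->T, C<->G on the code scale 1..4
    rc <- scan_codes(prof, rc_codes)
    hit_r <- which(!is.na(rc$mss) & rc$mss >= mcut & rc$css >= ccut)
    if (length(hit_r)) {
      # offset j (1-based) on the reverse complement starts at forward
      # position n - (j - 1) - L (0-based)
      out <- rbind(out, data.frame(offset = n - (hit_r - 1L) - prof$L,
                                   strand = "-", mss = rc$mss[hit_r],
                                   css = rc$css[hit_r],
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Conservation-filtered matrix hits on an aligned window pair
#'
#' Scans the ungapped reference row of a promoter alignment for matrix
#' hits, then flags each hit as conserved when (a) no gap character
#' appears in either alignment row across the hit's columns and (b) the
#' other-species bases at exactly those columns, in the same orientation,
#' also reach both cutoffs. Conserved hits are always a subset of the
#' reference hits.
#'
#' @param pwm A [position_frequency_matrix()].
#' @param ref_text,other_text Equal-length alignment rows.
#' @param both_strands Scan both strands of the reference (default TRUE).
#' @inheritParams scan_sequence
#' @return Data.frame as [scan_sequence()] plus a logical `conserved`
#'   column; offsets are 0-based positions on the ungapped reference row.
#' @export
conserved_hits <- function(pwm, ref_text, other_text, both_strands = TRUE,
                           matrix_cutoff = NULL, core_cutoff = NULL) {
  ref_text <- toupper(ref_text); other_text <- toupper(other_text)
  if (nchar(ref_text) != nchar(other_text))
    stop("alignment rows must have equal length", call. = FALSE)
  mcut <- if (is.null(matrix_cutoff)) pwm$matrix_cutoff else matrix_cutoff
  ccut <- if (is.null(core_cutoff)) pwm$core_cutoff else core_cutoff
  ref_chars <- strsplit(ref_text, "")[[1]]
  oth_chars <- strsplit(other_text, "")[[1]]
  colmap <- which(ref_chars != "-")
  refseq <- paste(ref_chars[colmap], collapse = "")
  hits <- scan_sequence(pwm, refseq, both_strands, matrix_cutoff = mcut,
                        core_cutoff = ccut)
  L <- ncol(pwm$freq)
  hits$conserved <- vapply(seq_len(nrow(hits)), function(k) {
    span <- colmap[hits$offset[k] + 1]:colmap[hits$offset[k] + L]
    if (any(ref_chars[span] == "-") || any(oth_chars[span] == "-"))
      return(FALSE)
    oth <- paste(oth_chars[span], collapse = "")
    if (grepl("[^ACGT]", oth)) return(FALSE)
    if (hits$strand[k] == "-") oth <- revcomp(oth)
    sc <- match_scores(pwm, oth)
    sc$mss >= mcut && sc$css >= ccut
  }, logical(1))
  hits
}
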