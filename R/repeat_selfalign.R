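# Substitution matrix used by the unit aligner: BLOSUM62 values restricted
# to the 20 standard residues (bundled constant via Biostrings).
submatrix_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA20, AA20]
    }
    cache
  }
})

#' Segment a protein into annotated repeat units
#'
#' Extracts repeat-unit sequences from annotated boundaries (e.g. the blades
#' or propellers of a beta-propeller protein). Boundaries are inputs, as in
#' annotation-driven repeat analysis; de-novo unit discovery is out of scope.
#'
#' @param protein amino-acid string.
#' @param boundaries data.frame with `start`, `end` columns, 1-based
#'   inclusive, sorted, non-overlapping; at least 2 units.
#' @param protein_id identifier carried on the result.
#' @return object of class `repeat_unit_set`: list with `protein_id`,
#'   `protein`, and `units` (data.frame `start`, `end`, `sequence`).
#' @export
segment_units <- function(protein, boundaries, protein_id = "protein") {
  stopifnot(is.character(protein), length(protein) == 1L)
  protein <- toupper(protein)
  b <- as.data.frame(boundaries)[, c("start", "end")]
  b$start <- as.integer(b$start); b$end <- as.integer(b$end)
  if (nrow(b) < 2L) stop_var("self-analysis requires at least 2 units")
  if (any(b$start < 1L | b$end > nchar(protein) | b$end < b$start))
    stop_var("unit boundaries out of range")
  if (is.unsorted(b$start, strictly = TRUE))
    stop_var("unit boundaries must be sorted")
  if (any(b$start[-1] <= b$end[-nrow(b)]))
    stop_var("unit boundaries overlap")
  b$sequence <- substring(protein, b$start, b$end)
  structure(list(protein_id = protein_id, protein = protein, units = b),
            class = "repeat_unit_set")
}

#' @export
print.repeat_unit_set <- function(x, ...) {
  cat(sprintf("<repeat_unit_set %s> %d units over %d aa\n", x$protein_id,
              nrow(x$units), nchar(x$protein)))
  invisible(x)
}

# Gap model shared by the pairwise and profile aligners: a gap run of length
# k costs gap_open + k * gap_extend (opening charges open + extend).
GAP_OPEN <- 10
GAP_EXTEND <- 1

# Gotoh global alignment on a score function f(i, j) giving the substitution
# score of position i of the "top" object (profile columns or sequence a)
# against position j of sequence b. Returns the traceback as a move string
# of D (consume both), U (consume top, gap in b), L (consume b, gap in top),
# with deterministic tie-breaking: diagonal, then up, then left.
gotoh_moves <- function(n, m, score_fun,
                        gap_open = GAP_OPEN, gap_extend = GAP_EXTEND) {
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)   # last move diagonal
  X <- matrix(NEG, n + 1L, m + 1L)   # last move up (gap in b)
  Y <- matrix(NEG, n + 1L, m + 1L)   # last move left (gap in top)
  # predecessor state per matrix: 1 = M, 2 = X, 3 = Y
  pM <- matrix(0L, n + 1L, m + 1L)
  pX <- matrix(0L, n + 1L, m + 1L)
  pY <- matrix(0L, n + 1L, m + 1L)
  M[1, 1] <- 0
  open1 <- gap_open + gap_extend
  if (n > 0) for (i in seq_len(n)) {
    X[i + 1L, 1L] <- -(gap_open + i * gap_extend)
    pX[i + 1L, 1L] <- if (i == 1L) 1L else 2L
  }
  if (m > 0) for (j in seq_len(m)) {
    Y[1L, j + 1L] <- -(gap_open + j * gap_extend)
    pY[1L, j + 1L] <- if (j == 1L) 1L else 3L
  }
  pick <- function(cands) which.max(cands)  # ties -> lowest index = M > X > Y
  for (i in seq_len(n)) {
    srow <- vapply(seq_len(m), function(j) score_fun(i, j), numeric(1))
    for (j in seq_len(m)) {
      ii <- i + 1L; jj <- j + 1L
      cand <- c(M[ii - 1L, jj - 1L], X[ii - 1L, jj - 1L], Y[ii - 1L, jj - 1L])
      k <- pick(cand)
      M[ii, jj] <- cand[k] + srow[j]
      pM[ii, jj] <- k
      cand <- c(M[ii - 1L, jj] - open1, X[ii - 1L, jj] - gap_extend,
                Y[ii - 1L, jj] - open1)
      k <- pick(cand)
      X[ii, jj] <- cand[k]
      pX[ii, jj] <- k
      cand <- c(M[ii, jj - 1L] - open1, X[ii, jj - 1L] - open1,
                Y[ii, jj - 1L] - gap_extend)
      k <- pick(cand)
      Y[ii, jj] <- cand[k]
      pY[ii, jj] <- k
    }
  }
  ii <- n + 1L; jj <- m + 1L
  state <- pick(c(M[ii, jj], X[ii, jj], Y[ii, jj]))
  score <- c(M[ii, jj], X[ii, jj], Y[ii, jj])[state]
  moves <- character(0)
  while (ii > 1L || jj > 1L) {
    if (state == 1L) {
      moves <- c("D", moves)
      prev <- pM[ii, jj]; ii <- ii - 1L; jj <- jj - 1L
    } else if (state == 2L) {
      moves <- c("U", moves)
      prev <- pX[ii, jj]; ii <- ii - 1L
    } else {
      moves <- c("L", moves)
      prev <- pY[ii, jj]; jj <- jj - 1L
    }
    state <- prev
  }
  list(moves = moves, score = score)
}

#' Optimal global pairwise alignment of two unit sequences
#'
#' Needleman-Wunsch/Gotoh global alignment under BLOSUM62 substitution
#' scores with affine gaps (a gap of length k costs 10 + k). Traceback
#' tie-break is deterministic: diagonal, then up (gap in `b`), then left.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param gap_open,gap_extend positive gap penalties (defaults 10 and 1).
#' @return list with `a_gapped`, `b_gapped` (equal-length gapped strings) and
#'   `score`.
#' @export
pairwise_unit_align <- function(a, b, gap_open = GAP_OPEN,
                                gap_extend = GAP_EXTEND) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  bad <- setdiff(unique(c(av, bv)), AA20)
  if (length(bad)) stop_var("unknown residue symbol(s): ",
                            paste(bad, collapse = ", "))
  sub <- submatrix_blosum62()
  res <- gotoh_moves(length(av), length(bv),
                     function(i, j) sub[av[i], bv[j]],
                     gap_open, gap_extend)
  ga <- gb <- character(length(res$moves))
  i <- j <- 0L
  for (k in seq_along(res$moves)) {
    mv <- res$moves[k]
    if (mv != "L") { i <- i + 1L; ga[k] <- av[i] } else ga[k] <- "-"
    if (mv != "U") { j <- j + 1L; gb[k] <- bv[j] } else gb[k] <- "-"
  }
  list(a_gapped = paste(ga, collapse = ""),
       b_gapped = paste(gb, collapse = ""), score = res$score)
}

#' Progressive self-alignment of repeat units
#'
#' Aligns the units of a repeat protein against each other: units are added
#' in input order to a growing profile (Gotoh alignment where a profile
#' column scores as the mean BLOSUM62 value of its non-gap residues against
#' the incoming residue; gaps carry the affine penalties). Row order equals
#' unit order; ungapping any row recovers its unit sequence.
#'
#' @param units a `repeat_unit_set` from [segment_units()], or a character
#'   vector of at least two unit sequences.
#' @return object of class `unit_alignment`: list with `rows` (named gapped
#'   strings of equal length) and `column_count`.
#' @export
self_align <- function(units) {
  seqs <- if (inherits(units, "repeat_unit_set")) units$units$sequence
          else as.character(units)
  if (length(seqs) < 2L) stop_var("self-analysis requires at least 2 units")
  sub <- submatrix_blosum62()
  profile <- matrix(strsplit(toupper(seqs[1]), "")[[1]], nrow = 1L)
  for (s in seqs[-1]) {
    sv <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(unique(c(profile[profile != "-"], sv)), AA20)
    if (length(bad)) stop_var("unknown residue symbol(s): ",
                              paste(bad, collapse = ", "))
    colscore <- function(i, j) {
      col <- profile[, i]
      res <- col[col != "-"]
      if (length(res) == 0L) return(0)
      mean(sub[res, sv[j]])
    }
    mv <- gotoh_moves(ncol(profile), length(sv), colscore)$moves
    newp <- matrix("-", nrow = nrow(profile) + 1L, ncol = length(mv))
    i <- j <- 0L
    for (k in seq_along(mv)) {
      if (mv[k] != "L") { i <- i + 1L
        newp[seq_len(nrow(profile)), k] <- profile[, i] }
      if (mv[k] != "U") { j <- j + 1L; newp[nrow(newp), k] <- sv[j] }
    }
    profile <- newp
  }
  rows <- apply(profile, 1L, paste, collapse = "")
  names(rows) <- paste0("unit_", seq_along(rows))
  structure(list(rows = rows, column_count = ncol(profile)),
            class = "unit_alignment")
}

#' @export
print.unit_alignment <- function(x, ...) {
  cat(sprintf("<unit_alignment> %d rows x %d columns\n", length(x$rows),
              x$column_count))
  invisible(x)
}

#' Per-column conservation profile of a unit alignment
#'
#' For each alignment column the score is the frequency of the modal non-gap
#' residue among non-gap symbols, down-weighted by the non-gap fraction of
#' the column, so insertion columns present in few units score low. The
#' consensus carries the modal residue, or `'-'` where gaps dominate
#' (more gaps than residues). Modal ties break alphabetically for
#' determinism.
#'
#' @param aln a `unit_alignment` from [self_align()] (or a character vector
#'   of equal-length gapped rows).
#' @return object of class `conservation_profile`: list with `scores`
#'   (fractions, one per column) and `consensus` (string).
#' @export
conservation_profile <- function(aln) {
  rows <- if (inherits(aln, "unit_alignment")) aln$rows
          else as.character(aln)
  if (length(unique(nchar(rows))) != 1L)
    stop_var("alignment rows must have equal length")
  mat <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(mat)
  scores <- numeric(ncol(mat))
  consensus <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (length(res) == 0L) { scores[j] <- 0; consensus[j] <- "-"; next }
    tab <- table(res)
    modal <- sort(names(tab)[tab == max(tab)])[1]
    scores[j] <- (max(tab) / length(res)) * (length(res) / n)
    consensus[j] <- if (n - length(res) > length(res)) "-" else modal
  }
  structure(list(scores = scores,
                 consensus = paste(consensus, collapse = "")),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns, mean score %.3f\n",
              length(x$scores), mean(x$scores)))
  invisible(x)
}
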