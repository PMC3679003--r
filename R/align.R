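# Global protein alignment (affine gaps) with deterministic tie-breaking,
# used to transfer bovine-rhodopsin residue numbering onto query opsins.

.asResidueString <- function(x) {
  if (is(x, "AAStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    x <- x[[1L]]
  }
  if (is(x, "AAString")) x <- as.character(x)
  toupper(as.character(x))
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Validate an opsin protein sequence
#'
#' Checks that the sequence uses only the 20 canonical one-letter amino
#' acid codes plus X, and is at least `minLen` residues long.
#'
#' @param x character string, `AAString`, or length-1 `AAStringSet`.
#' @param minLen minimal length (default 50).
#' @return the validated upper-case residue string, invisibly usable
#'   downstream.
#' @export
validateOpsinSequence <- function(x, minLen = 50) {
  s <- .asResidueString(x)
  letters <- strsplit(s, "")[[1L]]
  bad <- setdiff(unique(letters), c(.AA20, "X"))
  if (length(bad))
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  if (nchar(s) < minLen)
    stop("sequence shorter than ", minLen, " residues")
  s
}

#' Global alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh global alignment under a substitution matrix
#' (default BLOSUM62) with affine gap cost `gapOpen + L * gapExt` for a
#' gap of length L. Tie-breaking during traceback is deterministic:
#' at equal score a match/mismatch column is preferred over a gap in the
#' query, which is preferred over a gap in the reference.
#'
#' @param query,reference sequences (character, `AAString`, or length-1
#'   `AAStringSet`); non-empty.
#' @param gapOpen,gapExt gap opening / extension penalties (positive).
#' @param submat substitution matrix name in Biostrings (default
#'   `"BLOSUM62"`) or a numeric matrix with residue dimnames.
#' @return an object of class `OpsinAlignment`: list with `score`,
#'   `alignedQuery`, `alignedReference` (gapped strings), and `columns`
#'   (data.frame `qpos`/`rpos`, NA at gaps).
#' @examples
#' globalAlign("ACDEFG", "ACEFG")$alignedReference
#' @export
globalAlign <- function(query, reference, gapOpen = 10, gapExt = 1,
                        submat = "BLOSUM62") {
  q <- .asResidueString(query)
  r <- .asResidueString(reference)
  if (!nchar(q) || !nchar(r)) stop("empty sequence")
  if (is.character(submat)) {
    e <- new.env()
    utils::data(list = submat, package = "Biostrings", envir = e)
    submat <- get(submat, envir = e)
  }
  qs <- strsplit(q, "")[[1L]]
  rs <- strsplit(r, "")[[1L]]
  n <- length(qs); m <- length(rs)
  S <- submat[qs, rs, drop = FALSE]

  negInf <- -Inf
  M <- Ix <- Iy <- matrix(negInf, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  jj <- seq_len(m)
  Ix[, 1L] <- c(negInf, -(gapOpen + seq_len(n) * gapExt))
  Iy[1L, ] <- c(negInf, -(gapOpen + jj * gapExt))
  for (i in seq_len(n)) {
    # gap in reference (query residue i over '-'): extend down column
    Ix[i + 1L, ] <- pmax(Ix[i, ] - gapExt, M[i, ] - gapOpen - gapExt)
    # match/mismatch from the previous row's diagonal
    best <- pmax(M[i, jj], Ix[i, jj], Iy[i, jj])
    M[i + 1L, jj + 1L] <- best + S[i, ]
    # gap in query ('-' over reference residue j): cummax collapse
    Iy[i + 1L, jj + 1L] <- cummax(c(M[i + 1L, jj] + jj * gapExt))[jj] -
      gapOpen - (jj + 1L) * gapExt
    Iy[i + 1L, 1L] <- negInf
  }

  states <- c(M[n + 1L, m + 1L], Iy[n + 1L, m + 1L], Ix[n + 1L, m + 1L])
  score <- max(states)
  state <- c("M", "Iy", "Ix")[which(states >= score - 1e-9)[1L]]

  qa <- ra <- character(0)
  qpos <- rpos <- integer(0)
  i <- n; j <- m
  eq <- function(x, y) is.finite(x) && abs(x - y) <= 1e-9
  while (i > 0L || j > 0L) {
    if (state == "M") {
      qa <- c(qs[i], qa); ra <- c(rs[j], ra)
      qpos <- c(i, qpos); rpos <- c(j, rpos)
      target <- M[i + 1L, j + 1L] - S[i, j]
      i <- i - 1L; j <- j - 1L
      state <- if (eq(M[i + 1L, j + 1L], target)) "M" else
        if (eq(Iy[i + 1L, j + 1L], target)) "Iy" else "Ix"
    } else if (state == "Iy") {  # gap in query, consumes reference residue
      qa <- c("-", qa); ra <- c(rs[j], ra)
      qpos <- c(NA_integer_, qpos); rpos <- c(j, rpos)
      target <- Iy[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (eq(M[i + 1L, j + 1L] - gapOpen - gapExt, target)) "M"
               else "Iy"
    } else {  # Ix: gap in reference, consumes query residue
      qa <- c(qs[i], qa); ra <- c("-", ra)
      qpos <- c(i, qpos); rpos <- c(NA_integer_, rpos)
      target <- Ix[i + 1L, j + 1L]
      i <- i - 1L
      state <- if (eq(M[i + 1L, j + 1L] - gapOpen - gapExt, target)) "M"
               else "Ix"
    }
  }
  structure(list(score = score,
                 alignedQuery = paste(qa, collapse = ""),
                 alignedReference = paste(ra, collapse = ""),
                 columns = data.frame(qpos = qpos, rpos = rpos),
                 query = q, reference = r),
            class = "OpsinAlignment")
}

#' @export
print.OpsinAlignment <- function(x, ...) {
  cat(sprintf("OpsinAlignment: score %g, %d columns\n", x$score,
              nrow(x$columns)))
  invisible(x)
}

#' Map a reference position onto the query through an alignment
#'
#' Returns the 1-based query position aligned to the given 1-based
#' reference position, or NA when the homologous residue is deleted from
#' the query (the gap sentinel). Over non-gap columns the mapping is
#' injective.
#'
#' @param alignment an `OpsinAlignment` from [globalAlign()].
#' @param refPos 1-based position(s) in the reference.
#' @return integer query position(s), NA at gaps.
#' @export
mapReferencePosition <- function(alignment, refPos) {
  stopifnot(inherits(alignment, "OpsinAlignment"))
  nref <- nchar(alignment$reference)
  if (any(refPos < 1L | refPos > nref))
    stop("reference position out of range 1..", nref)
  idx <- match(refPos, alignment$columns$rpos)
  alignment$columns$qpos[idx]
}
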