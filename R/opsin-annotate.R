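# Opsin sequence annotation: Schiff-base lysine and counterion positions in
# bovine-rhodopsin numbering, plus configurable C-terminal motif scanning.

#' AnnotatedOpsin: residue-level annotation of a query opsin
#'
#' Positions are 1-based indices into the query sequence, homologous (via
#' global alignment) to the stated bovine-rhodopsin positions; NA when the
#' homologous residue is deleted from the query.
#'
#' @slot id query sequence id.
#' @slot posSchiff,resSchiff query position and residue homologous to the
#'   chromophore-binding lysine (bovine rhodopsin 296).
#' @slot pos113,res113,pos181,res181 counterion candidate positions
#'   (bovine rhodopsin numbering 113 and 181) and their query residues.
#'   Which of the two acts as the functional counterion distinguishes
#'   opsin lineages; the annotation reports identities only.
#' @slot hasSchiffLysine TRUE when the 296-homolog residue is K.
#' @slot motifHits data.frame `pattern`/`start`/`end` of motif matches in
#'   the C-terminal third.
#' @slot score alignment score against the reference.
#'
#' @exportClass AnnotatedOpsin
setClass("AnnotatedOpsin",
  representation(id = "character", posSchiff = "integer",
                 resSchiff = "character", pos113 = "integer",
                 res113 = "character", pos181 = "integer",
                 res181 = "character", hasSchiffLysine = "logical",
                 motifHits = "data.frame", score = "numeric"))

setMethod("show", "AnnotatedOpsin", function(object) {
  fmt <- function(p, r) if (is.na(p)) "gap" else sprintf("%s%d", r, p)
  cat(sprintf(paste0("AnnotatedOpsin '%s' (alignment score %g)\n",
                     "  Schiff-base (ref 296): %s%s\n",
                     "  counterion ref 113: %s | ref 181: %s\n",
                     "  motif hits: %d\n"),
              object@id, object@score,
              fmt(object@posSchiff, object@resSchiff),
              if (isTRUE(object@hasSchiffLysine)) " [K present]" else "",
              fmt(object@pos113, object@res113),
              fmt(object@pos181, object@res181),
              nrow(object@motifHits)))
})

#' Bundled bovine rhodopsin reference sequence
#'
#' The 348-residue bovine rhodopsin protein (UniProt P02699), shipped as a
#' plain FASTA file. It anchors the residue-numbering convention used
#' throughout opsin biology: the chromophore-binding Schiff-base lysine is
#' residue 296, the classical vertebrate counterion is E113, and the
#' ancestral counterion position is 181.
#'
#' @return a `Biostrings::AAStringSet` of length 1.
#' @export
bovineRhodopsin <- function() {
  path <- system.file("extdata", "bovine_rhodopsin_P02699.fasta",
                      package = "OpsinAssays", mustWork = TRUE)
  Biostrings::readAAStringSet(path)
}

#' Read opsin sequences from a FASTA file
#'
#' @param path FASTA file of protein sequences.
#' @param minLen minimal accepted length.
#' @return a validated `Biostrings::AAStringSet`.
#' @export
readOpsinFasta <- function(path, minLen = 50) {
  seqs <- Biostrings::readAAStringSet(path)
  for (i in seq_along(seqs)) validateOpsinSequence(seqs[[i]], minLen)
  seqs
}

# "simple character-class" motif pattern -> regular expression:
# upper-case residue letters are literal, [..] groups are alternatives,
# 'x'/'.' match any residue.
.motifToRegex <- function(pattern) {
  if (!grepl("^(\\[[A-Z]+\\]|[A-Zx.])+$", pattern))
    stop("pattern syntax error: ", pattern)
  gsub("x", ".", pattern, fixed = TRUE)
}

#' Scan motif patterns over (part of) a sequence
#'
#' @param seq residue string.
#' @param patterns named character vector of patterns (residue letters,
#'   `[...]` classes, `x`/`.` wildcards).
#' @param from 1-based start of the scanned region (default 1).
#' @return data.frame `pattern`, `start`, `end` in full-sequence 1-based
#'   coordinates.
#' @export
scanMotifs <- function(seq, patterns, from = 1L) {
  s <- .asResidueString(seq)
  region <- substring(s, from)
  hits <- list()
  for (nm in names(patterns)) {
    rx <- .motifToRegex(patterns[[nm]])
    m <- gregexpr(rx, region)[[1L]]
    if (m[1L] != -1L) {
      hits[[length(hits) + 1L]] <- data.frame(
        pattern = nm, start = as.integer(m) + from - 1L,
        end = as.integer(m) + attr(m, "match.length") + from - 2L)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(pattern = character(), start = integer(),
                  end = integer())
}

#' Annotate an opsin against the bovine rhodopsin reference
#'
#' Globally aligns the query to the reference and maps the positions that
#' carry the photopigment logic: the Schiff-base lysine homolog (reference
#' 296; its mutation to alanine abolishes light responses) and the two
#' counterion candidate positions (reference 113 and 181). User-supplied
#' C-terminal fingerprint motifs are scanned over the C-terminal third of
#' the query; none are bundled as defaults.
#'
#' @param query sequence (character, `AAString`, length-1 `AAStringSet`).
#' @param reference reference sequence; default [bovineRhodopsin()].
#' @param motifPatterns named character vector of motif patterns, or NULL.
#' @param id query id; defaults to the `AAStringSet` name or `"query"`.
#' @param ... passed to [globalAlign()].
#' @return an [AnnotatedOpsin-class].
#' @examples
#' ann <- annotateOpsin(bovineRhodopsin())
#' ann@resSchiff  # "K"
#' @export
annotateOpsin <- function(query, reference = bovineRhodopsin(),
                          motifPatterns = NULL, id = NULL, ...) {
  if (is.null(id))
    id <- if (is(query, "AAStringSet") && !is.null(names(query)))
      names(query)[1L] else "query"
  qs <- validateOpsinSequence(query)
  rs <- validateOpsinSequence(reference)
  aln <- globalAlign(qs, rs, ...)
  res <- strsplit(qs, "")[[1L]]
  pick <- function(refPos) {
    p <- mapReferencePosition(aln, refPos)
    list(pos = p, res = if (is.na(p)) NA_character_ else res[p])
  }
  schiff <- pick(296L); c113 <- pick(113L); c181 <- pick(181L)
  nq <- nchar(qs)
  ctermFrom <- as.integer(floor(2 * nq / 3)) + 1L
  hits <- if (is.null(motifPatterns))
    data.frame(pattern = character(), start = integer(), end = integer())
  else scanMotifs(qs, motifPatterns, from = ctermFrom)
  new("AnnotatedOpsin", id = id,
      posSchiff = as.integer(schiff$pos), resSchiff = schiff$res,
      pos113 = as.integer(c113$pos), res113 = c113$res,
      pos181 = as.integer(c181$pos), res181 = c181$res,
      hasSchiffLysine = identical(schiff$res, "K"),
      motifHits = hits, score = aln$score)
}

#' Coerce an annotation to a one-row data.frame
#'
#' @param ann an [AnnotatedOpsin-class].
#' @return one-row data.frame (motif hits collapsed to a `;`-separated
#'   string).
#' @export
annotationAsDataFrame <- function(ann) {
  hits <- if (nrow(ann@motifHits))
    paste(sprintf("%s:%d-%d", ann@motifHits$pattern, ann@motifHits$start,
                  ann@motifHits$end), collapse = ";") else ""
  data.frame(id = ann@id, pos_schiff = ann@posSchiff,
             res_schiff = ann@resSchiff, has_schiff_lysine =
               ann@hasSchiffLysine, pos_counterion_113 = ann@pos113,
             res_counterion_113 = ann@res113,
             pos_counterion_181 = ann@pos181,
             res_counterion_181 = ann@res181,
             motif_hits = hits, score = ann@score)
}

#' Nearest reference by alignment score (heuristic)
#'
#' Aligns a query against a set of labelled reference sequences and
#' reports them ordered by decreasing alignment score. This is a crude
#' similarity ranking, not a phylogenetic placement; tree inference is out
#' of scope and published tools should be used for it.
#'
#' @param query query sequence.
#' @param references named `AAStringSet` (or named character vector).
#' @param ... passed to [globalAlign()].
#' @return data.frame `id`/`score`, best first.
#' @export
nearestReference <- function(query, references, ...) {
  qs <- .asResidueString(query)
  ids <- names(references)
  if (is.null(ids)) stop("references must be named")
  scores <- vapply(seq_along(references), function(i)
    globalAlign(qs, .asResidueString(references[i]), ...)$score, numeric(1))
  out <- data.frame(id = ids, score = scores)
  out[order(-out$score), , drop = FALSE]
}
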