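# VH/VL annotation: closest-germline assignment by global alignment,
# motif-anchored region delineation, and per-region replacement counting.
#
# CDR3 is delineated purely from sequence anchors: the residues strictly
# between the last Cys preceding the J motif and the first residue of the
# motif itself (W of W-G-x-G for heavy chains, F of F-G-x-G for kappa).
# CDR1/CDR2 use fixed Kabat-style offsets, taken from the assigned
# germline's recorded layout when available. All coordinates are 0-based
# half-open internally.

aa_substitution_matrix <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 20, 20, dimnames = list(.AA20, .AA20))
  diag(m) <- match
  m
}

default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = 5, gap_ext = 1)
}

align_pair <- function(queries, ref_seq, scoring = default_scoring()) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), ref_seq,
    substitutionMatrix = aa_substitution_matrix(scoring$match, scoring$mismatch),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
    type = "global")
}

#' Assign the closest germline reference
#'
#' Aligns the query globally against every reference and returns the one
#' with the fewest amino-acid replacements (alignment mismatches). Ties are
#' broken deterministically by reference order.
#'
#' @param query amino-acid sequence (>= 60 residues, standard alphabet).
#' @param references a `germline_set` data.frame (rows of one chain).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   alignment scores (defaults +1/-1/5/1).
#' @return list with `germline_id`, `replacements` (mismatch count against
#'   the winner), `all_replacements` (named vector over all references) and
#'   `alignment` (the winning `PairwiseAlignments` object).
#' @examples
#' g <- generate_germlines(2, seed = 1)
#' assign_germline(g$sequence[1], g)$germline_id  # "VH1a1", 0 replacements
#' @export
assign_germline <- function(query, references, scoring = default_scoring()) {
  check_aa(query, "query")
  if (nchar(query) < 60) stop("query must be at least 60 residues")
  if (is.null(references) || !nrow(references))
    stop("empty germline reference set")
  mism <- vapply(references$sequence, function(r)
    Biostrings::nmismatch(align_pair(query, r, scoring)), numeric(1))
  names(mism) <- references$id
  best <- which.min(mism)  # first minimum = reference-order tie-break
  list(germline_id = references$id[best],
       replacements = unname(mism[best]),
       all_replacements = mism,
       alignment = align_pair(query, references$sequence[best], scoring))
}

#' Delineate framework and CDR regions
#'
#' Finds CDR3 between the last Cys preceding the chain's J motif
#' (exclusive) and the motif's first residue (exclusive); FR4 runs from the
#' motif onward. CDR1/CDR2 come from fixed Kabat-style offsets, overridable
#' per germline. Sequences missing either anchor are flagged as annotation
#' failures rather than dropped.
#'
#' @param query amino-acid sequence.
#' @param chain `"heavy"` or `"kappa"`.
#' @param cdr_offsets optional list with integer vectors `cdr1`, `cdr2`
#'   (0-based half-open) overriding the chain defaults.
#' @return object of class `region_annotation`: list with `ok`, `chain`,
#'   0-based half-open `boundaries` (named list fr1..fr4) and
#'   `cdr3_sequence`; on failure `ok = FALSE` and a `reason`.
#' @examples
#' r <- delineate_regions("ASTLDKEAKNTLYYCARDFGYWGQGTLVTISS", "heavy")
#' r$cdr3_sequence  # "ARDFGY"
#' @export
delineate_regions <- function(query, chain = c("heavy", "kappa"),
                              cdr_offsets = NULL) {
  chain <- match.arg(chain)
  check_aa(query, "query")
  fail <- function(reason)
    structure(list(ok = FALSE, chain = chain, reason = reason),
              class = "region_annotation")

  motif_hits <- gregexpr(.J_MOTIF[[chain]], query)[[1]]
  if (motif_hits[1] == -1) return(fail("missing J motif"))
  cys_hits <- gregexpr("C", query, fixed = TRUE)[[1]]
  if (cys_hits[1] == -1) return(fail("missing Cys anchor"))

  j_start <- NA_integer_; cys <- NA_integer_
  for (m in motif_hits) {        # first motif with a preceding Cys
    before <- cys_hits[cys_hits < m]
    if (length(before)) { j_start <- m; cys <- max(before); break }
  }
  if (is.na(j_start)) return(fail("no Cys precedes the J motif"))

  cys0 <- cys - 1L; j0 <- j_start - 1L      # to 0-based
  cdr3_len <- j0 - cys0 - 1L
  if (cdr3_len < 1 || cdr3_len > 40)
    return(fail(sprintf("CDR3 length %d outside 1-40", cdr3_len)))

  off <- if (is.null(cdr_offsets)) .CDR_OFFSETS[[chain]] else cdr_offsets
  c1 <- as.integer(off$cdr1); c2 <- as.integer(off$cdr2)
  if (c1[1] < 1 || c1[2] <= c1[1] || c2[1] <= c1[2] || c2[2] <= c2[1] ||
      c2[2] > cys0)
    return(fail("CDR1/CDR2 offsets incompatible with anchor positions"))

  boundaries <- list(
    fr1 = c(0L, c1[1]), cdr1 = c1, fr2 = c(c1[2], c2[1]), cdr2 = c2,
    fr3 = c(c2[2], cys0 + 1L), cdr3 = c(cys0 + 1L, j0),
    fr4 = c(j0, nchar(query)))
  structure(list(ok = TRUE, chain = chain, boundaries = boundaries,
                 cdr3_sequence = substr(query, cys0 + 2L, j0)),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  if (!x$ok) {
    cat("Region annotation FAILED:", x$reason, "\n")
    return(invisible(x))
  }
  cat("Region annotation (", x$chain, " chain, 0-based half-open)\n", sep = "")
  b <- do.call(rbind, x$boundaries)
  colnames(b) <- c("start", "end")
  print(b)
  cat("CDR3:", x$cdr3_sequence, "\n")
  invisible(x)
}

region_of <- function(pos0, boundaries) {
  for (nm in names(boundaries)) {
    b <- boundaries[[nm]]
    if (pos0 >= b[1] && pos0 < b[2]) return(nm)
  }
  NA_character_
}

#' Count replacement mutations per region
#'
#' Counts substitutions (aligned position, different residue) between a
#' query and its germline, attributed to the query's regions. Indel columns
#' are excluded: the reported numbers are replacement mutations only.
#' FR totals cover FR1-FR3 and CDR totals CDR1-CDR3; FR4 is J-encoded and
#' excluded.
#'
#' @param query amino-acid sequence.
#' @param germline germline sequence (or one-row `germline_set`).
#' @param regions a [delineate_regions()] result for the query.
#' @param alignment optional precomputed `PairwiseAlignments` of query vs
#'   germline; computed if missing.
#' @param scoring alignment scores, see [assign_germline()].
#' @return named numeric vector `c(fr, cdr, total)` with a `by_region`
#'   attribute giving the per-region breakdown.
#' @export
count_replacements <- function(query, germline, regions, alignment = NULL,
                               scoring = default_scoring()) {
  if (is.data.frame(germline)) germline <- germline$sequence[1]
  if (!isTRUE(regions$ok)) stop("cannot count replacements: annotation failed")
  if (is.null(alignment)) alignment <- align_pair(query, germline, scoring)
  p <- strsplit(as.character(Biostrings::alignedPattern(alignment)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(alignment)), "")[[1]]
  by_region <- stats::setNames(numeric(length(regions$boundaries)),
                               names(regions$boundaries))
  qpos <- -1L
  for (i in seq_along(p)) {
    if (p[i] != "-") qpos <- qpos + 1L
    if (p[i] == "-" || s[i] == "-") next   # indel column: excluded
    if (p[i] != s[i]) {
      reg <- region_of(qpos, regions$boundaries)
      if (!is.na(reg)) by_region[reg] <- by_region[reg] + 1
    }
  }
  fr <- sum(by_region[c("fr1", "fr2", "fr3")])
  cdr <- sum(by_region[c("cdr1", "cdr2", "cdr3")])
  structure(c(fr = fr, cdr = cdr, total = fr + cdr), by_region = by_region)
}

#' Annotate a VH/VL repertoire
#'
#' Runs the full per-clone annotation: closest-germline assignment for each
#' chain, region delineation using the assigned germline's CDR1/CDR2
#' layout, and replacement counting per region. Clones failing annotation
#' are flagged (`annotation_ok = FALSE`) and excluded from region-dependent
#' columns but retained in the table.
#'
#' @param repertoire data.frame with columns `clone_id`, `animal`, `bleed`,
#'   `vh`, `vl` (plus any metadata, carried through), e.g. from
#'   [generate_repertoire()] or [read_repertoire()].
#' @param germlines `germline_set` with heavy and kappa references.
#' @param scoring alignment scores, see [assign_germline()].
#' @return data.frame of class `annotated_repertoire`: the input plus, per
#'   chain, `*_germline`, `*_repl_fr` (FR1-FR3), `*_repl_cdr` (CDR1-CDR3),
#'   `*_repl_cdr3`, `*_repl_total` and `*_repl_v` (FR + CDR1/2 only, the
#'   germline-templated V-segment load), the loop columns `cdr3_h`,
#'   `cdr3_l` with lengths, and `annotation_ok`.
#' @examples
#' g <- generate_germline_set(seed = 1)
#' rep <- generate_repertoire(repertoire_config(n_clones = 10, seed = 3), g)
#' ann <- annotate_repertoire(rep, g)
#' table(ann$vh_germline)
#' @export
annotate_repertoire <- function(repertoire, germlines,
                                scoring = default_scoring()) {
  stopifnot(all(c("clone_id", "vh", "vl") %in% names(repertoire)))
  out <- as.data.frame(repertoire)
  for (ch in c("vh", "vl")) {
    chain <- if (ch == "vh") "heavy" else "kappa"
    refs <- germlines[germlines$chain == chain, , drop = FALSE]
    if (!nrow(refs)) stop("no ", chain, " references in germline set")
    queries <- out[[ch]]

    mism <- sapply(seq_len(nrow(refs)), function(r)
      Biostrings::nmismatch(align_pair(queries, refs$sequence[r], scoring)))
    mism <- matrix(mism, nrow = length(queries))
    best <- apply(mism, 1, which.min)

    n <- length(queries)
    germ_id <- refs$id[best]
    fr <- cdr <- cdr3n <- total <- rep(NA_real_, n)
    cdr3 <- rep(NA_character_, n)
    ok <- rep(TRUE, n)
    for (i in seq_len(n)) {
      r <- best[i]
      offs <- if ("cdr1_start" %in% names(refs))
        list(cdr1 = c(refs$cdr1_start[r], refs$cdr1_end[r]),
             cdr2 = c(refs$cdr2_start[r], refs$cdr2_end[r])) else NULL
      reg <- delineate_regions(queries[i], chain, cdr_offsets = offs)
      if (!reg$ok) { ok[i] <- FALSE; next }
      cdr3[i] <- reg$cdr3_sequence
      counts <- count_replacements(queries[i], refs$sequence[r], reg,
                                   scoring = scoring)
      fr[i] <- counts["fr"]; cdr[i] <- counts["cdr"]
      cdr3n[i] <- attr(counts, "by_region")["cdr3"]
      total[i] <- counts["total"]
    }
    pre <- ch
    out[[paste0(pre, "_germline")]] <- germ_id
    out[[paste0(pre, "_repl_fr")]] <- fr
    out[[paste0(pre, "_repl_cdr")]] <- cdr
    out[[paste0(pre, "_repl_cdr3")]] <- cdr3n
    out[[paste0(pre, "_repl_total")]] <- total
    out[[paste0(pre, "_repl_v")]] <- total - cdr3n
    out[[if (ch == "vh") "cdr3_h" else "cdr3_l"]] <- cdr3
    ok_col <- if (ch == "vh") "vh_ok" else "vl_ok"
    out[[ok_col]] <- ok
  }
  out$cdr3_h_length <- nchar(out$cdr3_h)
  out$cdr3_l_length <- nchar(out$cdr3_l)
  out$annotation_ok <- out$vh_ok & out$vl_ok
  out$vh_ok <- out$vl_ok <- NULL
  structure(out, class = c("annotated_repertoire", "data.frame"))
}
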