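# Synthetic VH/VL repertoire generator.
#
# Emulates the sequence structure a rabbit immunisation campaign produces:
# a handful of germline V references per chain, clones derived from them by
# Poisson-distributed somatic replacement mutations, clone-defining CDR3
# loops with a truncated discrete Gaussian length law, and a configurable
# fraction of clones grouped into shared-clonotype lineages whose CDR3s
# differ by at most a couple of replacements. Ground-truth labels
# (germline, clonotype, placed mutation counts) ride along so downstream
# annotation and clustering can be scored against the truth.
#
# Synthetic sequences restrict non-anchor positions to an alphabet without
# Cys and Gly, so the single conserved Cys and the J-segment W/F-G-x-G
# motif planted by the generator remain the only anchor candidates and
# region delineation is always well-posed.

# region layout of a generated germline of given chain/length:
# FR1 | CDR1 | FR2 | CDR2 | FR3(..Cys) | CDR3 | J motif + FR4 tail
germline_layout <- function(chain, length) {
  germ_cdr3 <- if (chain == "heavy") 10L else 9L
  j_start <- length - 10L            # 4-residue motif + 6-residue tail
  cys <- j_start - germ_cdr3 - 1L
  off <- .CDR_OFFSETS[[chain]]
  if (cys < off$cdr2[2] + 3L) {      # short domain: squeeze CDR1/2 in
    off <- list(cdr1 = round(c(0.30, 0.40) * cys),
                cdr2 = round(c(0.55, 0.73) * cys))
  }
  list(cdr1 = as.integer(off$cdr1), cdr2 = as.integer(off$cdr2),
       cys = as.integer(cys), j_start = as.integer(j_start),
       germ_cdr3 = germ_cdr3)
}

rand_aa <- function(n) paste(sample(.SAFE_AA, n, replace = TRUE), collapse = "")

#' Generate synthetic germline V-region references
#'
#' Builds `n` distinct amino-acid references of one chain, each with the
#' two anchors region delineation requires: a single conserved Cys closing
#' FR3 and a J-segment motif (`W-G-x-G` for heavy, `F-G-x-G` for kappa)
#' opening FR4. CDR1/CDR2 coordinates are recorded per reference so
#' annotation can delineate clones derived from them.
#'
#' @param n number of references (>= 1).
#' @param length domain length in residues (>= 60; default 110).
#' @param seed integer RNG seed.
#' @param chain `"heavy"` or `"kappa"`.
#' @return data.frame of class `germline_set` with columns `id`, `chain`,
#'   `sequence` and the 0-based layout columns `cdr1_start`, `cdr1_end`,
#'   `cdr2_start`, `cdr2_end`, `cys_pos`, `j_start`.
#' @examples
#' g <- generate_germlines(2, seed = 1)
#' regmatches(g$sequence[1], regexpr("WG.G", g$sequence[1]))
#' @export
generate_germlines <- function(n, length = 110, seed = 1,
                               chain = c("heavy", "kappa")) {
  chain <- match.arg(chain)
  if (n < 1) stop("n must be >= 1")
  if (length < 60) stop("germline length must be >= 60 residues")
  set.seed(seed)
  lay <- germline_layout(chain, length)
  seqs <- character(0)
  while (base::length(seqs) < n) {
    body <- strsplit(rand_aa(length), "")[[1]]
    body[lay$cys + 1L] <- "C"
    body[(lay$j_start + 1L):(lay$j_start + 4L)] <- strsplit(.J_SEED[[chain]], "")[[1]]
    s <- paste(body, collapse = "")
    if (!s %in% seqs) seqs <- c(seqs, s)
  }
  prefix <- if (chain == "heavy") "VH1a" else "VK1-"
  structure(
    data.frame(id = paste0(prefix, seq_len(n)), chain = chain,
               sequence = seqs,
               cdr1_start = lay$cdr1[1], cdr1_end = lay$cdr1[2],
               cdr2_start = lay$cdr2[1], cdr2_end = lay$cdr2[2],
               cys_pos = lay$cys, j_start = lay$j_start,
               stringsAsFactors = FALSE),
    class = c("germline_set", "data.frame"))
}

#' Generate a combined heavy + kappa germline reference set
#'
#' @param n_heavy,n_kappa references per chain.
#' @param length domain length in residues.
#' @param seed integer RNG seed.
#' @return `germline_set` data.frame with both chains.
#' @export
generate_germline_set <- function(n_heavy = 2, n_kappa = 2, length = 110,
                                  seed = 1) {
  h <- generate_germlines(n_heavy, length, seed = derive_seed(seed, 1), chain = "heavy")
  k <- generate_germlines(n_kappa, length, seed = derive_seed(seed, 2), chain = "kappa")
  structure(rbind(h, k), class = c("germline_set", "data.frame"))
}

#' Truncated discrete Gaussian CDR3 length law
#'
#' Probability weights proportional to a Gaussian density evaluated on an
#' integer support. The default (mean 11.4, sd 2.7 on 4-19) reproduces the
#' reported rabbit CDR-H3 length distribution.
#'
#' @param mean,sd Gaussian location and spread in residues.
#' @param support integer lengths with positive probability.
#' @return named numeric vector of probabilities summing to 1; names are
#'   the lengths.
#' @examples
#' law <- cdr3_length_law()
#' sum(as.integer(names(law)) * law)  # about 11.4
#' @export
cdr3_length_law <- function(mean = 11.4, sd = 2.7, support = 4:19) {
  w <- stats::dnorm(support, mean, sd)
  stats::setNames(w / sum(w), support)
}

draw_lengths <- function(n, law) {
  sample(as.integer(names(law)), n, replace = TRUE, prob = law)
}

#' Repertoire simulation configuration
#'
#' Study-scale defaults: 227 clones from 3 animals over 4 bleeds, a mean of
#' 13 somatic replacements per V region, CDR-H3 lengths from
#' [cdr3_length_law()] and a quarter of the clones placed into shared
#' clonotype lineages (about 75% unique clones).
#'
#' @param n_clones number of clones.
#' @param n_animals,n_bleeds numbers of animals (named 68, 69, ...) and
#'   bleeds (1, 2, ...).
#' @param shm_rate Poisson mean of somatic replacement mutations per chain,
#'   placed uniformly over non-anchor framework/CDR1/CDR2 positions.
#' @param cdr3_length_law CDR-H3 length law (named probability vector, see
#'   [cdr3_length_law()]).
#' @param cdr3_length_law_light CDR-L3 length law; kappa loops are shorter
#'   and less variable than heavy ones.
#' @param lineage_fraction fraction of clones belonging to multi-member
#'   lineages (shared clonotypes).
#' @param lineage_mutations maximum CDR3 replacements (per chain) between a
#'   lineage member and its founder, 0-2.
#' @param seed integer RNG seed.
#' @return validated list of class `repertoire_config`.
#' @export
repertoire_config <- function(n_clones = 227, n_animals = 3, n_bleeds = 4,
                              shm_rate = 13,
                              cdr3_length_law = rabscreen::cdr3_length_law(),
                              cdr3_length_law_light =
                                rabscreen::cdr3_length_law(9, 1.5, 5:14),
                              lineage_fraction = 0.25,
                              lineage_mutations = 2,
                              seed = 1) {
  stopifnot(n_clones >= 1, n_animals >= 1, n_bleeds >= 1)
  if (shm_rate < 0) stop("shm_rate must be >= 0")
  if (lineage_fraction < 0 || lineage_fraction > 1)
    stop("lineage_fraction must be in [0, 1]")
  if (abs(sum(cdr3_length_law) - 1) > 1e-8 ||
      abs(sum(cdr3_length_law_light) - 1) > 1e-8)
    stop("CDR3 length laws must sum to 1")
  if (!lineage_mutations %in% 0:2)
    stop("lineage_mutations must be 0, 1 or 2")
  structure(list(n_clones = as.integer(n_clones),
                 n_animals = as.integer(n_animals),
                 n_bleeds = as.integer(n_bleeds),
                 shm_rate = shm_rate,
                 cdr3_length_law = cdr3_length_law,
                 cdr3_length_law_light = cdr3_length_law_light,
                 lineage_fraction = lineage_fraction,
                 lineage_mutations = as.integer(lineage_mutations),
                 seed = as.integer(seed)),
            class = "repertoire_config")
}

mutate_positions <- function(chars, positions) {
  for (p in positions) {
    old <- chars[p]
    chars[p] <- sample(setdiff(.SAFE_AA, old), 1)
  }
  chars
}

# founder germline -> clone sequence: swap in a clone CDR3, then place m
# substitutions uniformly over positions strictly before the conserved Cys
build_clone_chain <- function(germ_seq, lay, cdr3, n_mut) {
  pre <- substr(germ_seq, 1L, lay$cys + 1L)               # ..FR3 incl Cys
  post <- substr(germ_seq, lay$j_start + 1L, nchar(germ_seq))  # J motif + tail
  chars <- strsplit(paste0(pre, cdr3, post), "")[[1]]
  mutable <- seq_len(lay$cys)                              # before the Cys
  m <- min(n_mut, length(mutable))
  if (m > 0) chars <- mutate_positions(chars, sample(mutable, m))
  list(seq = paste(chars, collapse = ""), placed = m)
}

perturb_cdr3 <- function(cdr3, max_mut) {
  if (max_mut == 0) return(cdr3)
  m <- sample(0:max_mut, 1)
  if (m == 0) return(cdr3)
  chars <- strsplit(cdr3, "")[[1]]
  paste(mutate_positions(chars, sample(seq_along(chars), min(m, length(chars)))),
        collapse = "")
}

#' Generate a synthetic VH/VL clone repertoire
#'
#' Draws clonotypes (heavy + kappa germline choice and a fresh CDR3 pair),
#' groups a configured fraction of clones into lineages sharing a founder
#' clonotype with at most `lineage_mutations` CDR3 replacements per chain,
#' and applies Poisson somatic replacement mutations to each chain's
#' germline-templated positions. Anchor residues are never mutated, and
#' lineages never span animals.
#'
#' @param config a [repertoire_config()].
#' @param germlines a `germline_set` containing at least one heavy and one
#'   kappa reference (see [generate_germline_set()]).
#' @return data.frame of class `repertoire` with one row per clone:
#'   `clone_id`, `animal`, `bleed`, `sort_arm`, `vh`, `vl` and ground-truth
#'   columns `true_vh_germline`, `true_vl_germline`, `true_clonotype`,
#'   `true_vh_mutations`, `true_vl_mutations`, `in_lineage`.
#' @examples
#' g <- generate_germline_set(seed = 1)
#' rep <- generate_repertoire(repertoire_config(n_clones = 20, seed = 2), g)
#' table(rep$animal)
#' @export
generate_repertoire <- function(config, germlines) {
  stopifnot(inherits(config, "repertoire_config"))
  heavy <- germlines[germlines$chain == "heavy", , drop = FALSE]
  kappa <- germlines[germlines$chain == "kappa", , drop = FALSE]
  if (!nrow(heavy) || !nrow(kappa))
    stop("germline set must contain at least one heavy and one kappa reference")
  set.seed(config$seed)
  n <- config$n_clones
  animals <- as.character(68L + seq_len(config$n_animals) - 1L)

  # lineage structure: Binomial(n, lineage_fraction) members, grouped into
  # lineages of size 2-4 (a leftover single member joins the last lineage)
  in_lineage <- stats::rbinom(n, 1, config$lineage_fraction) == 1
  member_idx <- which(in_lineage)
  member_idx <- member_idx[sample.int(length(member_idx))]
  lineages <- list()
  while (length(member_idx) >= 2) {
    size <- min(sample(2:4, 1), length(member_idx))
    lineages[[length(lineages) + 1L]] <- member_idx[seq_len(size)]
    member_idx <- member_idx[-seq_len(size)]
  }
  if (length(member_idx) == 1) {
    if (length(lineages)) {
      lineages[[length(lineages)]] <- c(lineages[[length(lineages)]], member_idx)
    } else {
      in_lineage[member_idx] <- FALSE
    }
  }

  clonotype <- rep(NA_character_, n)
  animal <- rep(NA_character_, n)
  vh <- vl <- character(n)
  vh_germ <- vl_germ <- character(n)
  vh_mut <- vl_mut <- integer(n)

  lay_h <- germline_layout("heavy", nchar(heavy$sequence[1]))
  lay_k <- germline_layout("kappa", nchar(kappa$sequence[1]))

  make_founder <- function() {
    list(h_ref = sample(nrow(heavy), 1), k_ref = sample(nrow(kappa), 1),
         h3 = rand_aa(draw_lengths(1, config$cdr3_length_law)),
         l3 = rand_aa(draw_lengths(1, config$cdr3_length_law_light)))
  }
  emit_clone <- function(i, founder, ct_id, an, mutate_cdr3) {
    h3 <- founder$h3; l3 <- founder$l3
    if (mutate_cdr3) {
      h3 <- perturb_cdr3(h3, config$lineage_mutations)
      l3 <- perturb_cdr3(l3, config$lineage_mutations)
    }
    ch <- build_clone_chain(heavy$sequence[founder$h_ref], lay_h, h3,
                            stats::rpois(1, config$shm_rate))
    ck <- build_clone_chain(kappa$sequence[founder$k_ref], lay_k, l3,
                            stats::rpois(1, config$shm_rate))
    vh[i] <<- ch$seq; vl[i] <<- ck$seq
    vh_mut[i] <<- ch$placed; vl_mut[i] <<- ck$placed
    vh_germ[i] <<- heavy$id[founder$h_ref]; vl_germ[i] <<- kappa$id[founder$k_ref]
    clonotype[i] <<- ct_id; animal[i] <<- an
  }

  ct <- 0L
  for (lin in lineages) {
    ct <- ct + 1L
    founder <- make_founder()
    an <- sample(animals, 1)
    for (j in seq_along(lin))
      emit_clone(lin[j], founder, sprintf("ct%03d", ct), an, mutate_cdr3 = j > 1)
  }
  for (i in which(is.na(clonotype))) {
    ct <- ct + 1L
    emit_clone(i, make_founder(), sprintf("ct%03d", ct),
               sample(animals, 1), mutate_cdr3 = FALSE)
  }

  structure(
    data.frame(clone_id = sprintf("clone%03d", seq_len(n)),
               animal = animal,
               bleed = sample(seq_len(config$n_bleeds), n, replace = TRUE),
               sort_arm = sample(c("panned", "preinc"), n, replace = TRUE,
                                 prob = c(0.8, 0.2)),
               vh = vh, vl = vl,
               true_vh_germline = vh_germ, true_vl_germline = vl_germ,
               true_clonotype = clonotype,
               true_vh_mutations = vh_mut, true_vl_mutations = vl_mut,
               in_lineage = in_lineage,
               stringsAsFactors = FALSE),
    class = c("repertoire", "data.frame"))
}
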