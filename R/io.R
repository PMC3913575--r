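# Readers and writers for the campaign's exchange formats (FASTA sequence
# pairs + metadata CSV, long-format panel CSV, square competition CSV,
# YAML configuration) and the end-to-end campaign driver.

#' Read / write amino-acid FASTA
#'
#' Thin wrappers over Biostrings with the package's conventions: records
#' are data.frames (`id`, `description`, `sequence`), ids must be unique,
#' sequences are wrapped at 60 columns on write, and write-then-read is
#' the identity.
#'
#' @param path file path.
#' @param records data.frame with `id`, `sequence` and optional
#'   `description` columns.
#' @return `read_fasta` returns the records data.frame (zero rows for an
#'   empty file); `write_fasta` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  ss <- Biostrings::readAAStringSet(path)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  data.frame(id = unname(id), description = unname(desc),
             sequence = unname(as.character(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  ss <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  names(ss) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Write / read a repertoire as FASTA + metadata CSV
#'
#' One FASTA record per chain (`<clone_id>_VH` / `<clone_id>_VL`) and a
#' metadata CSV with the clone table's non-sequence columns.
#'
#' @param repertoire a `repertoire` data.frame (see
#'   [generate_repertoire()]).
#' @param fasta_path,meta_path output paths.
#' @return `write_repertoire` returns the paths invisibly;
#'   `read_repertoire` returns the reassembled clone data.frame.
#' @export
write_repertoire <- function(repertoire, fasta_path, meta_path) {
  recs <- data.frame(
    id = c(paste0(repertoire$clone_id, "_VH"),
           paste0(repertoire$clone_id, "_VL")),
    sequence = c(repertoire$vh, repertoire$vl), stringsAsFactors = FALSE)
  write_fasta(recs, fasta_path)
  meta <- repertoire[, setdiff(names(repertoire), c("vh", "vl")), drop = FALSE]
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(fasta = fasta_path, meta = meta_path))
}

#' @rdname write_repertoire
#' @export
read_repertoire <- function(fasta_path, meta_path) {
  recs <- read_fasta(fasta_path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if ("animal" %in% names(meta)) meta$animal <- as.character(meta$animal)
  chain <- sub("^.*_", "", recs$id)
  clone <- sub("_V[HL]$", "", recs$id)
  vh <- stats::setNames(recs$sequence[chain == "VH"], clone[chain == "VH"])
  vl <- stats::setNames(recs$sequence[chain == "VL"], clone[chain == "VL"])
  missing_vh <- setdiff(meta$clone_id, names(vh))
  missing_vl <- setdiff(meta$clone_id, names(vl))
  if (length(missing_vh) || length(missing_vl))
    stop("clones missing a chain record: ",
         paste(union(missing_vh, missing_vl), collapse = ", "))
  meta$vh <- unname(vh[meta$clone_id])
  meta$vl <- unname(vl[meta$clone_id])
  structure(meta, class = c("repertoire", "data.frame"))
}

#' Write / read a well panel as long-format CSV
#'
#' The canonical exchange format is long (`well_id`, `assay`, `value`);
#' truth-label columns are carried as extra assays prefixed `label_`.
#'
#' @param panel an `assay_panel` data.frame.
#' @param path CSV path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   the wide `assay_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  chans <- setdiff(names(panel), "well_id")
  long <- do.call(rbind, lapply(chans, function(ch) {
    v <- panel[[ch]]
    data.frame(well_id = panel$well_id,
               assay = if (is.logical(v)) paste0("label_", ch) else ch,
               value = as.numeric(v), stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("well_id", "assay", "value") %in% names(long)))
  wells <- unique(long$well_id)
  wide <- data.frame(well_id = wells, stringsAsFactors = FALSE)
  for (ch in unique(long$assay)) {
    sel <- long[long$assay == ch, ]
    v <- stats::setNames(sel$value, sel$well_id)[wells]
    if (startsWith(ch, "label_")) {
      wide[[sub("^label_", "", ch)]] <- as.logical(v)
    } else wide[[ch]] <- unname(v)
  }
  structure(wide, class = c("assay_panel", "data.frame"))
}

#' Write / read a square competition matrix CSV
#'
#' Header row and first column hold the antibody ids.
#'
#' @param matrix square numeric matrix (or `competition_matrix`).
#' @param path CSV path.
#' @return `write_competition_csv` returns `path` invisibly;
#'   `read_competition_csv` the named square matrix.
#' @export
write_competition_csv <- function(matrix, path) {
  m <- as_comp_matrix(matrix)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_competition_csv
#' @export
read_competition_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("competition CSV is not square")
  m
}

#' Campaign configuration
#'
#' Bundles the stage options of a full in-silico campaign run. Serialises
#' losslessly through YAML ([yaml::write_yaml()] / [yaml::read_yaml()]).
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; stage seeds are derived from it.
#' @param n_clones,n_wells simulation sizes.
#' @param clustering_threshold clonotype mismatch threshold.
#' @param calibrate logical; calibrate OD thresholds from the panel
#'   (otherwise the [funnel_config()] defaults are used).
#' @param funnel a [funnel_config()].
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(out_dir = tempfile("campaign"), seed = 1,
                            n_clones = 227, n_wells = 7644,
                            clustering_threshold = 2,
                            calibrate = TRUE,
                            funnel = funnel_config()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_clones = as.integer(n_clones),
                 n_wells = as.integer(n_wells),
                 clustering_threshold = clustering_threshold,
                 calibrate = calibrate, funnel = funnel),
            class = "campaign_config")
}

#' Run a full synthetic campaign
#'
#' Executes the computational pipeline end to end on synthetic inputs:
#' simulate panel + repertoire + competition matrix, calibrate OD
#' thresholds, gate the funnel, annotate the repertoire, cluster
#' clonotypes, summarise diversity, and bin epitopes. Every artifact is
#' written under `config$out_dir`; the run is deterministic given the
#' seed.
#'
#' @param config a [campaign_config()].
#' @return invisible list with all stage results (`panel`, `thresholds`,
#'   `funnel`, `repertoire`, `annotated`, `clustering`, `categories`,
#'   `length_stats`, `binning`).
#' @export
run_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  panel <- generate_panel(panel_config(n_wells = config$n_wells,
                                       seed = derive_seed(config$seed, 1)))
  write_panel_csv(panel, out("panel.csv"))

  fcfg <- config$funnel
  thresholds <- NULL
  if (config$calibrate) {
    cal <- list(hu = calibrate_threshold(panel$od_hu[!panel$is_binder]),
                cyno = calibrate_threshold(panel$od_cyno[!panel$is_cyno]),
                mu = calibrate_threshold(panel$od_mu[!panel$is_mu]))
    thresholds <- vapply(cal, `[[`, numeric(1), "threshold")
    fcfg$hu_pos <- thresholds[["hu"]]
    fcfg$cyno_pos <- thresholds[["cyno"]]
    fcfg$mu_pos <- thresholds[["mu"]]
    yaml::write_yaml(as.list(thresholds), out("thresholds.yaml"))
  }
  funnel <- apply_funnel(panel, fcfg)
  utils::write.csv(as.data.frame(funnel), out("funnel.csv"),
                   row.names = FALSE)

  germ <- generate_germline_set(seed = derive_seed(config$seed, 2))
  rep <- generate_repertoire(
    repertoire_config(n_clones = config$n_clones,
                      seed = derive_seed(config$seed, 3)), germ)
  write_repertoire(rep, out("repertoire.fasta"), out("repertoire_meta.csv"))
  ann <- annotate_repertoire(rep, germ)
  utils::write.csv(as.data.frame(ann), out("annotation.csv"),
                   row.names = FALSE)

  clustering <- cluster_clonotypes(ann, threshold = config$clustering_threshold)
  memb <- data.frame(clone_id = names(clustering$membership),
                     cluster = ifelse(is.na(clustering$membership), "unique",
                                      clustering$membership))
  utils::write.csv(memb, out("clusters.csv"), row.names = FALSE)
  categories <- categorize(clustering, ann)
  utils::write.csv(as.data.frame(categories), out("categories.csv"),
                   row.names = FALSE)
  length_stats <- cdr3_length_stats(ann, strata = c("animal", "bleed"))

  cm <- generate_competition(
    competition_config(seed = derive_seed(config$seed, 4)))
  write_competition_csv(cm, out("competition.csv"))
  binning <- bin_epitopes(cm)
  utils::write.csv(data.frame(antibody = names(binning$labels),
                              group = binning$labels),
                   out("epitope_groups.csv"), row.names = FALSE)

  invisible(list(panel = panel, thresholds = thresholds, funnel = funnel,
                 repertoire = rep, annotated = ann, clustering = clustering,
                 categories = categories, length_stats = length_stats,
                 binning = binning))
}
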