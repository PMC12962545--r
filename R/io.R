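# Readers, writers, validation and configuration for the pipeline's
# tab-separated inputs and outputs.  All tables are TSV with a header row;
# '#'-prefixed lines are comments.  Species names are matched
# case-sensitively after whitespace trimming, with spaces and underscores
# interchangeable (Newick convention).

#' Write a table as TSV with a provenance header
#'
#' Writes a '#' comment line recording the package version and seed, then
#' the table, tab-separated, at full double precision.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param seed seed recorded in the header (optional).
#' @param extra additional `key=value` strings for the header.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path, seed = NULL, extra = character(0)) {
  hdr <- sprintf("# mycofeedback %s%s%s",
                 as.character(packageVersion("mycofeedback")),
                 if (!is.null(seed)) sprintf("; seed=%d", as.integer(seed))
                 else "",
                 if (length(extra)) paste0("; ", paste(extra, collapse = "; "))
                 else "")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_mf("file not found: %s", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_mf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
}

#' Load and cross-validate a complete dataset
#'
#' Reads the five pipeline inputs (ASV counts + taxonomy, sample metadata,
#' host tree, feedback biomass table, growth-assay summaries), builds the
#' validated in-memory objects, and reports the numbers retained.
#'
#' @param paths named character vector (or list) with entries `counts`,
#'   `taxonomy`, `metadata`, `tree`, `feedback`, `assays` (the last two
#'   optional, `NA` to skip).
#' @param verbose print retention counts (default `TRUE`).
#' @return A list with `asv`, `meta`, `tree`, `feedback`, `assays`.
#' @export
load_dataset <- function(paths, verbose = TRUE) {
  cdf <- read_tsv(paths[["counts"]])
  .require_cols(cdf, "sample_id", paths[["counts"]])
  counts <- as.matrix(cdf[, setdiff(names(cdf), "sample_id"), drop = FALSE])
  rownames(counts) <- cdf$sample_id
  storage.mode(counts) <- "integer"
  tx <- read_tsv(paths[["taxonomy"]])
  .require_cols(tx, c("asv_id", "species"), paths[["taxonomy"]])
  asv <- asv_table(counts, setNames(tx$species, tx$asv_id))

  meta <- read_tsv(paths[["metadata"]])
  .require_cols(meta, c("sample_id", "host_species", "life_history",
                        "phylo_group", "block", "year"),
                paths[["metadata"]])
  bad_lh <- setdiff(unique(meta$life_history), c("early", "late"))
  if (length(bad_lh))
    stop_mf("%s: life_history outside {early, late}: %s",
            paths[["metadata"]], paste(bad_lh, collapse = ", "))
  missing_meta <- setdiff(rownames(counts), meta$sample_id)
  if (length(missing_meta))
    stop_mf("samples without metadata: %s",
            paste(missing_meta, collapse = ", "))

  if (!file.exists(paths[["tree"]])) stop_mf("file not found: %s",
                                             paths[["tree"]])
  tree <- ape::read.tree(paths[["tree"]])

  feedback <- NULL
  if (!is.null(paths[["feedback"]]) && !is.na(paths[["feedback"]])) {
    feedback <- read_tsv(paths[["feedback"]])
    .require_cols(feedback, c("host_species", "training_species", "block",
                              "replicate", "biomass"), paths[["feedback"]])
    if (any(feedback$biomass <= 0))
      stop_mf("%s: biomass must be positive", paths[["feedback"]])
  }
  assays <- NULL
  if (!is.null(paths[["assays"]]) && !is.na(paths[["assays"]])) {
    assays <- read_tsv(paths[["assays"]])
    .require_cols(assays, c("study_id", "host_species", "fungal_isolate",
                            "mean_inoc", "sd_inoc", "n_inoc", "mean_ctrl",
                            "sd_ctrl", "n_ctrl"), paths[["assays"]])
  }
  msg(verbose, "loaded %d samples, %d ASVs, %d fungal species, %d tree tips",
      nrow(counts), ncol(counts),
      length(setdiff(unique(asv$taxonomy), "unassigned")),
      length(tree$tip.label))
  list(asv = asv, meta = meta, tree = tree, feedback = feedback,
       assays = assays)
}

#' Validate a loaded dataset
#'
#' Report-only consistency checks: samples whose host species is absent
#' from the tree, feedback pairs missing any of the four interaction-
#' coefficient cells, assay records with fewer than 2 replicates, and
#' all-zero ASV columns.
#'
#' @param dataset list as returned by [load_dataset()].
#' @return An object of class `validation_report`; `$is_clean` is `TRUE`
#'   when every check passes.
#' @export
validate_dataset <- function(dataset) {
  rep_ <- list(
    hosts_not_on_tree = character(0),
    feedback_pairs_missing_cells = character(0),
    low_n_assays = integer(0),
    all_zero_asvs = character(0)
  )
  tips <- canon_species(dataset$tree$tip.label)
  rep_$hosts_not_on_tree <-
    sort(setdiff(canon_species(unique(dataset$meta$host_species)), tips))
  if (!is.null(dataset$feedback)) {
    fb <- dataset$feedback
    for (blk in unique(fb$block)) {
      d <- fb[fb$block == blk, ]
      sp <- sort(unique(c(d$host_species, d$training_species)))
      for (i in seq_along(sp)) for (j in seq_along(sp)) {
        if (j <= i) next
        A <- sp[i]; B <- sp[j]
        have <- c(
          Aa = any(d$host_species == A & d$training_species == A),
          Ab = any(d$host_species == A & d$training_species == B),
          Ba = any(d$host_species == B & d$training_species == A),
          Bb = any(d$host_species == B & d$training_species == B))
        if (!all(have))
          rep_$feedback_pairs_missing_cells <-
            c(rep_$feedback_pairs_missing_cells,
              sprintf("%s|%s|block=%s (missing %s)", A, B, blk,
                      paste(names(have)[!have], collapse = ",")))
      }
    }
  }
  if (!is.null(dataset$assays))
    rep_$low_n_assays <- which(dataset$assays$n_inoc < 2 |
                                 dataset$assays$n_ctrl < 2)
  zero <- colSums(dataset$asv$counts) == 0
  rep_$all_zero_asvs <- colnames(dataset$asv$counts)[zero]
  rep_$is_clean <- all(lengths(rep_[names(rep_) != "is_clean"]) == 0)
  structure(rep_, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$is_clean) {
    cat("validation: clean\n")
    return(invisible(x))
  }
  for (nm in setdiff(names(x), "is_clean"))
    if (length(x[[nm]]))
      cat(sprintf("%s (%d): %s\n", nm, length(x[[nm]]),
                  paste(head(x[[nm]], 10), collapse = ", ")))
  invisible(x)
}

#' Write pipeline result tables
#'
#' Writes each table of a named list as `<name>.tsv` under `out_dir`, with
#' provenance headers, and returns the manifest of written paths.
#'
#' @param tables named list of data.frames (may be empty).
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in each header.
#' @return Named character vector of file paths (empty for an empty list).
#' @export
write_results <- function(tables, out_dir, seed = NULL) {
  stopifnot(is.list(tables))
  if (!length(tables)) return(character(0))
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop_mf("result tables must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p, seed = seed)
    paths[nm] <- p
  }
  paths
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration: input `paths` plus analysis settings
#' (pseudocount, rarefaction depth/draws, permutation count, seed).
#' Missing settings take the defaults of [default_config()].
#'
#' @param path YAML file path.
#' @return A config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_mf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_config(), cfg)
  if (!is.null(out$n_perm) && out$n_perm < 99)
    stop_mf("permutation count must be >= 99")
  if (!is.null(out$rarefaction_depth) && out$rarefaction_depth < 1)
    stop_mf("rarefaction depth must be >= 1")
  out
}

#' Default pipeline configuration
#'
#' @return A list of analysis settings: `pseudocount`, `rarefaction_depth`,
#'   `rarefaction_draws`, `n_perm`, `seed`, `include_asv_level`,
#'   `feedback_year`.
#' @export
default_config <- function() {
  list(
    pseudocount = 1,
    rarefaction_depth = 100,
    rarefaction_draws = 100,
    n_perm = 999,
    seed = 1,
    include_asv_level = TRUE,
    feedback_year = 2
  )
}
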