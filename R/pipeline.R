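#' Run the census/dimorphism pipeline end to end
#'
#' Orchestrates the stages on synthetic or on-disk data: cohort simulation,
#' distance features, persistence diagrams, kernel Gram matrices, the
#' classification experiment, and the census arithmetic. Every stage's
#' outputs are files under `out_dir`, and a JSON manifest records inputs,
#' outputs, seeds and the package version; re-running the same
#' configuration reproduces all outputs (all randomness is seeded).
#'
#' @param config either a path to a YAML file or a list. Recognised entries:
#'   \describe{
#'     \item{`out_dir`}{output directory (created if needed).}
#'     \item{`seed`}{master seed (default 1).}
#'     \item{`stages`}{character vector among `"cohort"`, `"distances"`,
#'       `"tda"`, `"classify"`, `"stats"`; default all.}
#'     \item{`cohort`}{arguments for [cohort_spec()].}
#'     \item{`cohort_csv`}{read an existing coordinate table instead of
#'       simulating (see [read_point_cloud_table()]).}
#'     \item{`experiment`}{arguments for [experiment_config()].}
#'     \item{`lines_csv`}{per-line summary CSV for the `stats` stage
#'       (defaults to the packaged census table).}
#'   }
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config needs an `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("cohort", "distances", "tda", "classify", "stats")
  manifest <- list(
    package = "cnscensus",
    version = as.character(utils::packageVersion("cnscensus")),
    seed = seed, stages = stages, outputs = list()
  )
  note <- function(stage, path) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]], path)
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  clouds <- NULL
  if ("cohort" %in% stages) {
    tryCatch({
      if (!is.null(config$cohort_csv)) {
        clouds <- read_point_cloud_table(config$cohort_csv)
        manifest$inputs$cohort_csv <- config$cohort_csv
      } else {
        spec <- do.call(cohort_spec, c(config$cohort %||% list(),
                                       if (is.null(config$cohort$seed)) list(seed = seed)))
        clouds <- generate_cohort(spec)
        manifest$cohort_spec <- unclass(spec)
      }
      path <- file.path(out_dir, "cohort.csv")
      write_point_cloud_table(clouds, path)
      note("cohort", path)
    }, error = function(e) fail("cohort", e))
  }

  ec <- do.call(experiment_config, c(config$experiment %||% list(),
                                     if (is.null(config$experiment$master_seed)) list(master_seed = seed)))

  if ("distances" %in% stages && !is.null(clouds)) {
    tryCatch({
      fm <- feature_matrix(clouds)
      path <- file.path(out_dir, "distance_features.csv")
      utils::write.csv(
        data.frame(animal_id = rownames(fm), fm, row.names = NULL),
        path, row.names = FALSE
      )
      note("distances", path)
    }, error = function(e) fail("distances", e))
  }

  gram <- NULL
  sex <- NULL
  if ("tda" %in% stages && !is.null(clouds)) {
    tryCatch({
      cd <- cohort_diagrams(clouds, m = ec$subsample_size,
                            repeats = ec$subsample_repeats, seed = seed)
      sex <- cd$sex
      gram <- gram_matrix(cd$diagrams, cd$group_ids,
                          sigma = ec$heat_bandwidth_sigma)
      path <- file.path(out_dir, "gram.tsv")
      utils::write.table(gram$matrix, path, sep = "\t", col.names = NA)
      note("tda", path)
    }, error = function(e) fail("tda", e))
  }

  if ("classify" %in% stages && !is.null(gram)) {
    tryCatch({
      exp <- run_experiment(gram, sex, ec)
      path <- file.path(out_dir, "splits.csv")
      utils::write.csv(exp$per_split, path, row.names = FALSE)
      note("classify", path)
      spath <- file.path(out_dir, "classify_summary.json")
      jsonlite::write_json(
        list(overlap_fraction = exp$overlap_fraction,
             n_splits = nrow(exp$per_split)),
        spath, auto_unbox = TRUE, digits = NA
      )
      note("classify", spath)
    }, error = function(e) fail("classify", e))
  }

  if ("stats" %in% stages) {
    tryCatch({
      lines <- if (!is.null(config$lines_csv)) {
        utils::read.csv(config$lines_csv, stringsAsFactors = FALSE)
      } else {
        cns_line_counts()
      }
      rep <- census_report(lines, pooled = cns_pooled_counts())
      path <- file.path(out_dir, "census_report.json")
      jsonlite::write_json(
        list(
          pooled_neurons = rep$pooled_neurons,
          sex_diff = rep$sex_diff,
          line_vs_line = rep$line_vs_line,
          glia_fraction = rep$glia_fraction,
          channel = rep$channel
        ),
        path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
      note("stats", path)
    }, error = function(e) fail("stats", e))
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
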