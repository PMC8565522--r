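# Config-driven end-to-end orchestration: synth -> connectivity -> atlas ->
# metrics -> trajectories -> stats, with reproducible on-disk outputs.

#' Write a 3-D/4-D array as NIfTI with an affine
#'
#' @param arr numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr + 0)  # strip attributes, force numeric
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#'
#' @param path file path.
#' @return numeric array with attribute `affine`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  A <- RNifti::xform(img)
  attributes(A) <- list(dim = dim(A))
  attr(arr, "affine") <- A
  arr
}

#' Default pipeline configuration
#'
#' All tunable parameters of a run, as a plain nested list that serializes
#' losslessly to YAML. The defaults define the package's reference study
#' conditions: a 7-network phantom at 2 mm, bundles of 60 streamlines per
#' network with 1 mm endpoint jitter and 10% distractors, diffusion noise
#' calibrated per subregion to the default model's R^2, FA threshold 0.2,
#' population-atlas weighting.
#'
#' @param seed global seed; per-stage seeds are fanned out deterministically.
#' @param n_subjects cohort size.
#' @param K number of networks.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1, n_subjects = 20, K = 7) {
  list(seed = seed, K = K,
       phantom = list(voxel_size = c(2, 2, 2)),
       cohort = list(n = n_subjects, age_distribution = "uniform"),
       tractogram = list(bundle_count = 60, endpoint_jitter_mm = 1,
                         off_target_fraction = 0.1),
       diffusion = list(subject_sd = NULL, voxel_sd = NULL,
                        betas = list(tiv = 0, sex = 0, education = 0),
                        low_fa_prob = 0.5),
       metrics = list(fa_threshold = 0.2, weight_source = "population"),
       stages = list(connect = TRUE, atlas = TRUE, metrics = TRUE,
                     fit = TRUE, stats = TRUE),
       write_volumes = FALSE)
}

#' Run the full synthetic pipeline
#'
#' Executes (as enabled by `config$stages`): cohort + phantom synthesis,
#' per-subject tractogram generation and connectivity counting, population
#' atlas with hard segmentation and split-half Dice, subregional metric
#' extraction, quadratic trajectory fitting, and group statistics. Writes
#' TSV/JSON/NIfTI outputs plus the resolved configuration and a manifest
#' (seed, package version, output checksums) to `out_dir`. Identical
#' config and seed give byte-identical tabular outputs.
#'
#' @param config configuration list from [default_config()] (or a YAML file
#'   path).
#' @param out_dir output directory (created if needed); `NULL` runs fully
#'   in memory.
#' @return object of class `cc_run`: all stage products.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  }
  run <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # synth is always on: everything downstream consumes it
  run$phantom <- stage("synth", make_phantom(cfg$K,
                                             voxel_size = cfg$phantom$voxel_size))
  run$cohort <- stage("synth",
                      make_cohort(cfg$cohort$n, cfg$cohort$age_distribution,
                                  seed = stage_seed(cfg$seed, 1)))
  if (!is.null(out_dir))
    utils::write.table(run$cohort, file.path(out_dir, "cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  if (isTRUE(cfg$stages$connect)) {
    ph <- run$phantom
    dil <- dilate_labels(ph$network_labels, ph$voxel_size, 2)
    counts <- rep(cfg$tractogram$bundle_count, ph$K)
    names(counts) <- seq_len(ph$K)
    run$maps <- stage("connect", lapply(seq_len(nrow(run$cohort)), function(s) {
      tg <- make_tractogram(ph, counts,
                            endpoint_jitter_mm = cfg$tractogram$endpoint_jitter_mm,
                            off_target_fraction = cfg$tractogram$off_target_fraction,
                            seed = stage_seed(cfg$seed, 100 + s))
      cm <- count_connections(tg, ph$cc_mask, dil, ph$affine, K = ph$K,
                              subject_id = run$cohort$id[s],
                              voxel_size = ph$voxel_size)
      normalize_connections(cm)
    }))
    run$di_volumes <- stage("connect", lapply(seq_len(nrow(run$cohort)),
      function(s) make_diffusion_volumes(ph, run$cohort[s, ],
        seed = stage_seed(cfg$seed, 5000 + s),
        subject_sd = cfg$diffusion$subject_sd,
        voxel_sd = cfg$diffusion$voxel_sd,
        betas = unlist(cfg$diffusion$betas),
        low_fa_prob = cfg$diffusion$low_fa_prob)))
  }

  if (isTRUE(cfg$stages$atlas) && !is.null(run$maps)) {
    run$atlas <- stage("atlas", build_atlas(run$maps, run$phantom$cc_mask))
    run$hard_labels <- hard_segment(run$atlas)
    run$split_half <- stage("atlas",
      split_half(run$cohort, run$maps, run$phantom$cc_mask,
                 seed = stage_seed(cfg$seed, 2)))
    if (!is.null(out_dir)) {
      write_volume(run$atlas$probs, run$atlas$affine,
                   file.path(out_dir, "atlas_probs.nii.gz"))
      write_volume(run$hard_labels, run$atlas$affine,
                   file.path(out_dir, "hard_segmentation.nii.gz"))
      utils::write.table(
        data.frame(label = seq_len(run$atlas$K),
                   network = network_names(run$atlas$K)),
        file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(
        list(per_label = run$split_half$dice$per_label,
             weighted_mean = run$split_half$dice$weighted_mean,
             unweighted_mean = run$split_half$dice$unweighted_mean),
        file.path(out_dir, "dice.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  if (isTRUE(cfg$stages$metrics) && !is.null(run$maps)) {
    run$records <- stage("metrics",
      subject_records(run$cohort, run$maps, run$di_volumes, run$atlas,
                      fa_threshold = cfg$metrics$fa_threshold,
                      weight_source = cfg$metrics$weight_source))
    if (!is.null(out_dir)) {
      utils::write.table(run$records, file.path(out_dir, "records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(records_long(run$records),
                         file.path(out_dir, "records_long.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (isTRUE(cfg$stages$fit) && !is.null(run$records)) {
    run$trajectories <- stage("fit", fit_all(run$records))
    if (!is.null(out_dir))
      utils::write.table(trajectory_table(run$trajectories),
                         file.path(out_dir, "trajectories.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (isTRUE(cfg$stages$stats) && !is.null(run$records)) {
    nets <- network_names(cfg$K)
    run$group_comparisons <- stage("stats",
      lapply(stats::setNames(nets, nets), function(n)
        tryCatch(compare_age_groups(run$records, n),
                 error = function(e) NULL)))
    run$subregion_comparisons <- stage("stats",
      lapply(stats::setNames(c("FA", "MD", "RD", "AD"),
                             c("FA", "MD", "RD", "AD")),
             function(ix) compare_subregions(run$records, ix)))
    if (!is.null(out_dir)) {
      sig <- lapply(run$group_comparisons, function(g)
        if (is.null(g)) NULL
        else list(omnibus_p = g$omnibus$p_value,
                  significant_pairs = g$pairwise[g$pairwise$significant,
                                                 c("group_i", "group_j")]))
      jsonlite::write_json(sig, file.path(out_dir, "group_stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if (!is.null(out_dir)) {
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("cctopo")),
      r_version = as.character(getRversion()),
      stages_run = names(Filter(isTRUE, cfg$stages)),
      checksums = as.list(tools::md5sum(files[!grepl("manifest", files)])))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(run) <- "cc_run"
  run
}

# Wide records -> long (subject, network, index, value, value_residual).
records_long <- function(records) {
  pcols <- grep("^P\\.", names(records), value = TRUE)
  nets <- sub("^P\\.", "", pcols)
  rows <- list()
  for (ix in c("FA", "MD", "RD", "AD")) for (net in nets) {
    col <- paste0(ix, ".", net)
    if (!col %in% names(records)) next
    rows[[length(rows) + 1]] <-
      data.frame(subject_id = records$id, network = net, index = ix,
                 value = records[[col]],
                 value_residual = records[[paste0(col, ".resid")]])
  }
  do.call(rbind, rows)
}

#' @export
print.cc_run <- function(x, ...) {
  cat("Pipeline run: n =", nrow(x$cohort), "subjects, K =", x$config$K, "\n")
  if (!is.null(x$split_half))
    cat(sprintf("  split-half weighted Dice: %.4f\n",
                x$split_half$dice$weighted_mean))
  if (!is.null(x$trajectories))
    cat("  trajectory cells fitted:", sum(x$trajectories$status == "ok"),
        "\n")
  invisible(x)
}

#' Summarize a completed run directory
#'
#' Assembles the tabular outputs of [run_pipeline()] into a single text
#' report (`report.md` in the run directory). Sections whose stage outputs
#' are missing are omitted with a notice.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of report lines, invisibly; the report is also
#'   written to `<run_dir>/report.md`.
#' @export
make_report <- function(run_dir) {
  if (!dir.exists(run_dir) || !length(list.files(run_dir)))
    stop("run directory is empty or missing: ", run_dir)
  lines <- c("# Callosal topography run report", "")
  grab <- function(f) file.path(run_dir, f)

  if (file.exists(grab("cohort.tsv"))) {
    co <- utils::read.delim(grab("cohort.tsv"))
    lines <- c(lines, "## Cohort",
               sprintf("- %d subjects, ages %d-%d", nrow(co),
                       min(co$age), max(co$age)),
               sprintf("- groups: %s",
                       paste(names(table(co$age_group)),
                             table(co$age_group), sep = "=",
                             collapse = ", ")), "")
  } else lines <- c(lines, "_(cohort output missing)_", "")

  if (file.exists(grab("dice.json"))) {
    dj <- jsonlite::read_json(grab("dice.json"))
    lines <- c(lines, "## Split-half reproducibility",
               sprintf("- size-weighted mean Dice: %.4f",
                       dj$weighted_mean),
               sprintf("- unweighted mean Dice: %.4f", dj$unweighted_mean),
               "")
  } else lines <- c(lines, "_(atlas/Dice output missing)_", "")

  if (file.exists(grab("trajectories.tsv"))) {
    tt <- utils::read.delim(grab("trajectories.tsv"))
    lines <- c(lines, "## Aging trajectories (printing scales)",
               utils::capture.output(print(tt, row.names = FALSE,
                                           digits = 3)), "")
  } else lines <- c(lines, "_(trajectory output missing)_", "")

  if (file.exists(grab("group_stats.json"))) {
    gs <- jsonlite::read_json(grab("group_stats.json"))
    lines <- c(lines, "## Age-group comparisons",
               vapply(names(gs), function(n)
                 sprintf("- %s: omnibus p = %.4g", n,
                         as.numeric(gs[[n]]$omnibus_p %||% NA_real_)), ""),
               "")
  } else lines <- c(lines, "_(group statistics missing)_", "")

  writeLines(lines, grab("report.md"))
  invisible(lines)
}
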