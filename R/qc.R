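#' Blur filter configuration
#'
#' @param edge_sum_threshold Images with [edge_sum()] strictly below this
#'   value are excluded (default 5e4).
#' @param low,high Canny hysteresis thresholds on the 8-bit scale. The
#'   edge-sum threshold is only meaningful jointly with these, so all
#'   three are persisted in the consort report.
#' @param mode Edge score mode, see [edge_sum()].
#' @return List of class `edge_filter_config`.
#' @export
edge_filter_config <- function(edge_sum_threshold = 5e4,
                               low = 100, high = 200,
                               mode = c("sum", "count")) {
  check_number(edge_sum_threshold, "edge_sum_threshold", min = 0)
  check_number(low, "low", min = 0)
  check_number(high, "high", min = 0)
  if (low >= high) stop_field("low", "must be strictly below high")
  structure(list(edge_sum_threshold = edge_sum_threshold,
                 low = low, high = high, mode = match.arg(mode)),
            class = "edge_filter_config")
}

#' Blast-percentage filter configuration
#'
#' AML samples in which the blast-equivalent cell categories of the
#' routine differential blood count sum to less than `min_percent` are
#' excluded; 20% is the conventional WHO blast threshold for most AML
#' subtypes. The rule applies to AML classes only -- controls are exempt.
#'
#' @param blast_categories Manifest column names summed as the blast
#'   percentage.
#' @param min_percent Exclusion threshold in percent (strict `<`).
#' @param control_label Label of the exempt control class.
#' @return List of class `blast_filter_config`.
#' @export
blast_filter_config <- function(blast_categories = c("pct_myeloblasts",
                                                     "pct_promyelocytes",
                                                     "pct_myelocytes"),
                                min_percent = 20,
                                control_label = "control") {
  if (length(blast_categories) == 0L) {
    stop_field("blast_categories", "must be non-empty")
  }
  check_number(min_percent, "min_percent", min = 0, max = 100)
  structure(list(blast_categories = blast_categories,
                 min_percent = min_percent,
                 control_label = control_label),
            class = "blast_filter_config")
}

#' Exclude blurry single-cell images
#'
#' Partitions images into kept and excluded sets: an image is excluded iff
#' its Canny edge sum is strictly below the configured threshold.
#' Unreadable images are excluded with reason `"unreadable"`.
#'
#' @param paths Character vector of image file paths (TIFF), or a list of
#'   in-memory image arrays.
#' @param cfg An [edge_filter_config()].
#' @return List with `kept` and `excluded` (data.frames of `image`,
#'   `edge_sum`, `reason`); the two partition the input.
#' @export
filter_blurry <- function(paths, cfg = edge_filter_config()) {
  stopifnot(inherits(cfg, "edge_filter_config"))
  n <- length(paths)
  ids <- if (is.character(paths)) paths else
    names(paths) %||% sprintf("image%04d", seq_len(n))
  score <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    img <- tryCatch(
      if (is.character(paths)) read_cell_image(paths[i]) else paths[[i]],
      error = function(e) NULL)
    if (is.null(img)) {
      reason[i] <- "unreadable"
      next
    }
    score[i] <- edge_sum(img, low = cfg$low, high = cfg$high,
                         mode = cfg$mode)
    if (score[i] < cfg$edge_sum_threshold) reason[i] <- "blurry"
  }
  df <- data.frame(index = seq_len(n), image = ids, edge_sum = score,
                   reason = reason, stringsAsFactors = FALSE)
  list(kept = df[is.na(df$reason), c("index", "image", "edge_sum")],
       excluded = df[!is.na(df$reason), ])
}

#' Exclude low-blast AML patients
#'
#' An AML patient is excluded iff the sum of the configured blast-category
#' percentages is strictly below `cfg$min_percent`; a patient at exactly
#' the threshold is kept. Control patients are always kept (the criterion
#' is defined on AML samples).
#'
#' @param manifest Cohort manifest `data.frame` with `patient_id`, `label`
#'   and the blast-category columns for AML patients.
#' @param cfg A [blast_filter_config()].
#' @return List with `kept` and `excluded` manifest subsets; excluded rows
#'   gain `reason` and `blast_percent` columns.
#' @export
filter_low_blast <- function(manifest, cfg = blast_filter_config()) {
  stopifnot(inherits(cfg, "blast_filter_config"))
  is_aml <- manifest$label != cfg$control_label
  missing_cols <- setdiff(cfg$blast_categories, names(manifest))
  if (length(missing_cols) > 0L && any(is_aml)) {
    stop(sprintf("AML patient '%s' lacks blast column '%s'",
                 manifest$patient_id[is_aml][1L], missing_cols[1L]),
         call. = FALSE)
  }
  blast <- rep(NA_real_, nrow(manifest))
  if (any(is_aml)) {
    sub <- manifest[is_aml, cfg$blast_categories, drop = FALSE]
    if (anyNA(sub)) {
      bad <- which(is.na(rowSums(sub)))[1L]
      stop(sprintf("AML patient '%s' has missing blast percentages",
                   manifest$patient_id[is_aml][bad]), call. = FALSE)
    }
    blast[is_aml] <- rowSums(sub)
  }
  drop <- is_aml & blast < cfg$min_percent
  excluded <- manifest[drop, , drop = FALSE]
  if (nrow(excluded) > 0L) {
    excluded$reason <- "low_blast"
    excluded$blast_percent <- blast[drop]
  }
  list(kept = manifest[!drop, , drop = FALSE], excluded = excluded)
}

#' Apply expert manual exclusions
#'
#' Removes patients an expert flagged for insufficient quality. The
#' assessment itself happens outside the package; this only ingests the
#' verdicts. Unknown ids raise a warning and are ignored.
#'
#' @param manifest Cohort manifest `data.frame`.
#' @param exclusion_ids Character vector of patient ids to remove.
#' @return List with `kept` and `excluded` manifest subsets (excluded rows
#'   gain a `reason` column) and `unknown_ids`.
#' @export
apply_manual_exclusions <- function(manifest, exclusion_ids = character()) {
  unknown <- setdiff(exclusion_ids, manifest$patient_id)
  if (length(unknown) > 0L) {
    warning("unknown patient ids in exclusion list ignored: ",
            paste(unknown, collapse = ", "))
  }
  drop <- manifest$patient_id %in% exclusion_ids
  excluded <- manifest[drop, , drop = FALSE]
  if (nrow(excluded) > 0L) excluded$reason <- "manual_quality"
  list(kept = manifest[!drop, , drop = FALSE], excluded = excluded,
       unknown_ids = unknown)
}

#' Run the full data-cleaning cascade
#'
#' Applies the three cleaning stages in their canonical order -- per-image
#' blur exclusion, then per-patient blast-percentage exclusion, then
#' manual-quality exclusion -- and returns consort-style accounting of
#' image and patient counts before and after every stage.
#'
#' @param cohort A cohort as returned by [load_cohort()] with
#'   `images = TRUE`, or a list with `manifest` and `images` (named list
#'   of per-patient lists of image paths/arrays).
#' @param edge_cfg An [edge_filter_config()].
#' @param blast_cfg A [blast_filter_config()].
#' @param manual_exclusions Character vector of patient ids.
#' @return List of class `consort_report`: `manifest` (cleaned), `stages`
#'   (data.frame of per-stage image/patient counts), `image_exclusions`,
#'   `patient_exclusions`, `config`.
#' @export
run_qc_cascade <- function(cohort, edge_cfg = edge_filter_config(),
                           blast_cfg = blast_filter_config(),
                           manual_exclusions = character()) {
  manifest <- cohort$manifest
  images <- cohort$images
  n_img0 <- sum(lengths(images))

  # stage 1: per-image blur filter
  img_excl <- list()
  kept_images <- images
  for (pid in names(images)) {
    res <- filter_blurry(images[[pid]], edge_cfg)
    if (nrow(res$excluded) > 0L) {
      res$excluded$patient_id <- pid
      img_excl[[pid]] <- res$excluded
    }
    kept_images[[pid]] <- images[[pid]][res$kept$index]
  }
  img_excl <- if (length(img_excl)) do.call(rbind, img_excl) else
    data.frame(index = integer(), image = character(),
               edge_sum = numeric(), reason = character(),
               patient_id = character())
  n_img1 <- sum(lengths(kept_images))

  # stage 2: patient-level blast filter
  st2 <- filter_low_blast(manifest, blast_cfg)
  # stage 3: manual exclusions
  st3 <- apply_manual_exclusions(st2$kept, manual_exclusions)

  excl_cols <- function(df) {
    if (nrow(df) == 0L) {
      return(data.frame(patient_id = character(), label = character(),
                        reason = character()))
    }
    df[, c("patient_id", "label", "reason"), drop = FALSE]
  }
  pat_excl <- rbind(excl_cols(st2$excluded), excl_cols(st3$excluded))
  n_img2 <- sum(lengths(kept_images[names(kept_images) %in%
                                      st2$kept$patient_id]))
  kept_images <- kept_images[names(kept_images) %in% st3$kept$patient_id]

  stages <- data.frame(
    stage = c("input", "blur_filter", "blast_filter", "manual_exclusion"),
    n_images = c(n_img0, n_img1, n_img2, sum(lengths(kept_images))),
    n_patients = c(nrow(manifest), nrow(manifest), nrow(st2$kept),
                   nrow(st3$kept)))

  structure(list(
    manifest = st3$kept,
    images = kept_images,
    stages = stages,
    image_exclusions = img_excl,
    patient_exclusions = pat_excl,
    config = list(edge = unclass(edge_cfg), blast = unclass(blast_cfg),
                  manual_exclusions = manual_exclusions)
  ), class = "consort_report")
}

#' @export
print.consort_report <- function(x, ...) {
  cat("<consort_report>\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Serialize a consort report to JSON
#'
#' @param report A `consort_report` from [run_qc_cascade()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_consort_json <- function(report, path) {
  out <- list(stages = report$stages,
              image_exclusions = report$image_exclusions,
              patient_exclusions = report$patient_exclusions,
              config = report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
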