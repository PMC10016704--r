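#' Read a single-cell image
#'
#' Reads a TIFF (or PNG-decodable via [tiff::readTIFF]) single-cell image
#' into an H x W x 3 array with values in `[0, 1]`. Grayscale images are
#' expanded to three identical channels.
#'
#' @param path Image file path.
#' @return Numeric array H x W x 3.
#' @export
read_cell_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: '%s' does not exist", path),
         call. = FALSE)
  }
  img <- tiff::readTIFF(path)
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  } else if (dim(img)[3L] > 3L) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  }
  img
}

#' Write a single-cell image as 8-bit TIFF
#'
#' @param img H x W x 3 array with values in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_image <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  invisible(path)
}

# ---- feature-bag container -------------------------------------------------

#' Write a feature bag to disk
#'
#' One tab-separated file per patient: first column `cell_id` (the row
#' index joining features back to images), remaining columns `f1..fd`
#' feature values at full double precision. Row order is the bag order.
#'
#' @param bag A [new_bag()] object.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_bag <- function(bag, path) {
  df <- data.table::data.table(cell_id = bag$cell_ids)
  feat <- data.table::as.data.table(bag$features)
  data.table::setnames(feat, sprintf("f%d", seq_len(ncol(bag$features))))
  if (!is.null(bag$planted)) df$planted <- bag$planted
  data.table::fwrite(cbind(df, feat), path, sep = "\t")
  invisible(path)
}

#' Read a feature bag from disk
#'
#' @param path `.tsv` path written by [write_bag()].
#' @param patient_id,label,classes Bag metadata (stored in the manifest,
#'   not the bag file).
#' @return A [new_bag()] object.
#' @export
read_bag <- function(path, patient_id, label, classes = cytomil_classes()) {
  dt <- data.table::fread(path, sep = "\t")
  fcols <- grep("^f[0-9]+$", names(dt), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  planted <- if ("planted" %in% names(dt)) dt$planted else NULL
  new_bag(as.matrix(dt[, fcols, with = FALSE]), patient_id, label,
          classes = classes, cell_ids = dt$cell_id, planted = planted)
}

# ---- cohort layout ---------------------------------------------------------

#' Write a synthetic or extracted cohort to disk
#'
#' Lays out a cohort directory the readers expect: `manifest.tsv` at the
#' root plus either one feature-bag file per patient under `bags/` or one
#' image folder per patient with numbered TIFF files. If no manifest is
#' supplied one is synthesized with [synthesize_manifest()].
#'
#' @param bags List of [new_bag()] objects (feature mode), or NULL.
#' @param images Named list (by patient id) of image lists from
#'   [generate_cell_images()] (image mode), or NULL.
#' @param out_dir Output directory (created if needed).
#' @param manifest Optional manifest `data.frame`; must cover all patients.
#' @param low_blast_ids Passed to [synthesize_manifest()] when the
#'   manifest is synthesized.
#' @param seed Seed for manifest synthesis.
#' @return The manifest `data.frame`, invisibly, with a `path` column.
#' @export
write_cohort <- function(bags = NULL, images = NULL, out_dir,
                         manifest = NULL, low_blast_ids = character(),
                         seed = 1L) {
  if (is.null(bags) && is.null(images)) {
    stop_field("bags", "supply bags and/or images")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(manifest)) {
    if (is.null(bags)) stop_field("manifest", "required in image-only mode")
    manifest <- synthesize_manifest(bags, low_blast_ids = low_blast_ids,
                                    seed = seed)
  }
  manifest$path <- NA_character_
  if (!is.null(bags)) {
    bag_dir <- file.path(out_dir, "bags")
    dir.create(bag_dir, showWarnings = FALSE)
    for (b in bags) {
      rel <- file.path("bags", paste0(b$patient_id, ".tsv"))
      write_bag(b, file.path(out_dir, rel))
      manifest$path[manifest$patient_id == b$patient_id] <- rel
    }
  }
  if (!is.null(images)) {
    for (pid in names(images)) {
      pdir <- file.path(out_dir, pid)
      dir.create(pdir, showWarnings = FALSE)
      for (im in images[[pid]]) {
        write_cell_image(im$pixels,
                         file.path(pdir, paste0(im$image_id, ".tif")))
      }
      if (is.null(bags)) {
        manifest$path[manifest$patient_id == pid] <- pid
      }
    }
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Load a cohort directory
#'
#' Reads `manifest.tsv` and, depending on mode, the per-patient feature
#' bags or the per-patient image file lists (on-disk lexicographic order,
#' which is the frozen cell order for attention-image joins). Strict mode
#' fails on any inconsistency; lenient mode warns and skips.
#'
#' @param dir Cohort directory written by [write_cohort()].
#' @param mode `"bags"`, `"images"`, or `"auto"` (bags if present).
#' @param classes Allowed labels.
#' @param strict Fail (TRUE) or warn-and-skip (FALSE) on missing paths.
#' @return List of class `cytomil_cohort` with `manifest`, and `bags`
#'   (list of bags) or `images` (named list of per-patient image path
#'   vectors).
#' @export
load_cohort <- function(dir, mode = c("auto", "bags", "images"),
                        classes = cytomil_classes(), strict = TRUE) {
  mode <- match.arg(mode)
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) {
    stop(sprintf("no manifest.tsv in '%s'", dir), call. = FALSE)
  }
  manifest <- utils::read.delim(mf, stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$patient_id)) {
    stop_field("manifest", paste("duplicate patient id:",
                                 manifest$patient_id[
                                   duplicated(manifest$patient_id)][1L]))
  }
  bad <- setdiff(unique(manifest$label), classes)
  if (length(bad) > 0L) {
    stop_field("manifest", sprintf("unknown label '%s'; allowed: %s",
                                   bad[1L], paste(classes, collapse = ", ")))
  }
  if (mode == "auto") {
    mode <- if (dir.exists(file.path(dir, "bags"))) "bags" else "images"
  }
  out <- list(manifest = manifest)
  if (mode == "bags") {
    bags <- vector("list", nrow(manifest))
    keep <- rep(TRUE, nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      p <- file.path(dir, manifest$path[i])
      if (!file.exists(p)) {
        msg <- sprintf("bag file missing for patient '%s': %s",
                       manifest$patient_id[i], p)
        if (strict) stop(msg, call. = FALSE)
        warning(msg); keep[i] <- FALSE; next
      }
      bags[[i]] <- read_bag(p, manifest$patient_id[i], manifest$label[i],
                            classes = classes)
    }
    out$bags <- bags[keep]
    out$manifest <- manifest[keep, , drop = FALSE]
  } else {
    images <- list()
    keep <- rep(TRUE, nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      pdir <- file.path(dir, manifest$patient_id[i])
      if (!dir.exists(pdir)) {
        msg <- sprintf("image folder missing for patient '%s': %s",
                       manifest$patient_id[i], pdir)
        if (strict) stop(msg, call. = FALSE)
        warning(msg); keep[i] <- FALSE; next
      }
      images[[manifest$patient_id[i]]] <-
        sort(list.files(pdir, pattern = "\\.tif{1,2}$", full.names = TRUE))
    }
    out$images <- images
    out$manifest <- manifest[keep, , drop = FALSE]
  }
  class(out) <- "cytomil_cohort"
  out
}

#' @export
print.cytomil_cohort <- function(x, ...) {
  cat(sprintf("<cytomil_cohort> %d patients (%s mode)\n", nrow(x$manifest),
              if (!is.null(x$bags)) "feature-bag" else "image"))
  print(table(x$manifest$label))
  invisible(x)
}
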