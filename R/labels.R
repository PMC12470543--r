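# Expert-in-the-loop label application: the morphology catalog, validated
# cluster -> class assignment files, class directory construction and
# class distribution summaries.

#' The RBC morphology catalog
#'
#' The 43 leaf classes of the annotation scheme, grouped into eight
#' families (normocytes, staining alterations, erythrocyte inclusions,
#' hemoglobin-distribution variants, shape variants, leukocytes, platelets
#' and a residual group), in canonical order. The shipped table also
#' carries the reference class distribution of an expert-validated
#' 14,089-cell smear dataset, used by the percentage-regression tests,
#' and a flag for classes whose boundaries were refined by ellipse
#' fitting.
#'
#' @param counts include the reference `count` / `percentage` columns.
#' @return data.frame `family, class_name` (plus `count, percentage,
#'   ellipse_refined` when `counts = TRUE`), 43 rows.
#' @export
morphologyCatalog <- function(counts = FALSE) {
  cat <- read.csv(system.file("extdata", "morphology_catalog.csv",
                              package = "rbcmorph"),
                  stringsAsFactors = FALSE)
  if (counts) cat else cat[, c("family", "class_name")]
}

.assignmentHeader <- c("cluster_id", "class_name", "status", "reviewer",
                       "cycle")

#' Load and validate a cluster label assignment CSV
#'
#' The file interface to expert cluster review: one row per reviewed
#' cluster and cycle with header
#' `cluster_id,class_name,status,reviewer,cycle[,ellipse_filter]`.
#' `status` is one of confirmed / mixed / artifact; confirmed rows must
#' name a catalog class. Later cycles override earlier ones when applied.
#'
#' @param path CSV file path.
#' @return validated assignment data.frame (zero rows, with a warning,
#'   for an empty file).
#' @export
loadAssignment <- function(path) {
  a <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(.assignmentHeader %in% names(a))) {
    stop("assignment CSV must have columns ",
         paste(.assignmentHeader, collapse = ","))
  }
  if (!"ellipse_filter" %in% names(a)) {
    a$ellipse_filter <- rep(NA_character_, nrow(a))
  }
  if (nrow(a) == 0L) {
    warning("empty assignment file: ", path)
    return(a)
  }
  if (!all(a$status %in% c("confirmed", "mixed", "artifact"))) {
    stop("status must be one of confirmed, mixed, artifact")
  }
  dup <- duplicated(a[, c("cluster_id", "cycle")])
  if (any(dup)) {
    stop("duplicate cluster ids within one cycle: ",
         paste(unique(a$cluster_id[dup]), collapse = ", "))
  }
  catalog <- morphologyCatalog()$class_name
  bad <- a$status == "confirmed" & !a$class_name %in% catalog
  if (any(bad)) {
    stop("unknown class name(s): ",
         paste(unique(a$class_name[bad]), collapse = ", "),
         "\nvalid catalog classes: ", paste(catalog, collapse = ", "))
  }
  a
}

# parse "field=value" ellipse filters into a predicate over class paths
.ellipseFilterKeep <- function(filter, classPath) {
  if (is.na(filter) || !nzchar(filter)) return(rep(TRUE, length(classPath)))
  kv <- strsplit(filter, "=", fixed = TRUE)[[1]]
  if (length(kv) != 2L) stop("malformed ellipse_filter: ", filter)
  grepl(paste0(kv[2], "/"), classPath, fixed = TRUE)
}

#' Apply a validated assignment to cluster directories
#'
#' Members of confirmed clusters are copied under
#' `<outDir>/<class_name>/`; mixed and artifact clusters go to
#' `<outDir>/_review/cluster_<id>/`. When several review cycles assign the
#' same cluster, the highest cycle wins. A row's optional
#' `ellipse_filter` (e.g. `shape_group=Pencil`) restricts the confirmed
#' copy to members whose morphometric class path matches; the rest are
#' routed to review.
#'
#' @param clusterDir root holding `cluster_<id>/` directories (as written
#'   by [exportClusterDirs()]).
#' @param assignment data.frame from [loadAssignment()].
#' @param outDir output root.
#' @param metrics optional [runEllipsePipeline()] data.frame, required
#'   when any row carries an `ellipse_filter`.
#' @return invisible data.frame of per-class file counts.
#' @export
applyAssignment <- function(clusterDir, assignment, outDir,
                            metrics = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(assignment)) {
    # keep the highest review cycle per cluster
    assignment <- assignment[order(assignment$cluster_id,
                                   -assignment$cycle), ]
    assignment <- assignment[!duplicated(assignment$cluster_id), ]
  }
  for (i in seq_len(nrow(assignment))) {
    row <- assignment[i, ]
    src <- file.path(clusterDir, sprintf("cluster_%02d", row$cluster_id))
    if (!dir.exists(src)) {
      src2 <- file.path(clusterDir, paste0("cluster_", row$cluster_id))
      if (dir.exists(src2)) src <- src2 else
        stop("missing cluster directory for cluster ", row$cluster_id)
    }
    files <- list.files(src, pattern = "\\.png$", full.names = TRUE)
    files <- files[basename(files) != "montage.png"]
    toReview <- function(fs) {
      if (!length(fs)) return(invisible())
      rd <- file.path(outDir, "_review",
                      sprintf("cluster_%02d", row$cluster_id))
      dir.create(rd, recursive = TRUE, showWarnings = FALSE)
      file.copy(fs, file.path(rd, basename(fs)), overwrite = TRUE)
    }
    if (row$status != "confirmed") {
      toReview(files)
      next
    }
    keep <- rep(TRUE, length(files))
    if (!is.na(row$ellipse_filter) && nzchar(row$ellipse_filter)) {
      if (is.null(metrics)) {
        stop("assignment uses ellipse_filter but no metrics were supplied")
      }
      m <- metrics[match(basename(files), metrics$file), ]
      keep <- .ellipseFilterKeep(row$ellipse_filter, m$class_path) &
        !is.na(m$class_path)
    }
    dest <- file.path(outDir, row$class_name)
    dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    if (any(keep)) {
      file.copy(files[keep], file.path(dest, basename(files[keep])),
                overwrite = TRUE)
    }
    toReview(files[!keep])
  }
  invisible(summarizeClasses(outDir))
}

#' Summarise a class directory tree (or counts) as a distribution table
#'
#' Percentages are `100 * count / total` rounded to 2 decimals. Classes
#' are ordered as in the catalog; unknown directories are appended.
#' Files under `_review/` are excluded from the totals.
#'
#' @param x either the root of a class directory tree, or a named numeric
#'   vector of per-class counts.
#' @param csv optional output path for the summary CSV (header
#'   `family,class_name,count,percentage`).
#' @return data.frame `family, class_name, count, percentage` with the
#'   grand total in attribute `"total"`.
#' @export
summarizeClasses <- function(x, csv = NULL) {
  if (is.character(x) && length(x) == 1L) {
    dirs <- list.dirs(x, recursive = FALSE)
    dirs <- dirs[basename(dirs) != "_review"]
    counts <- vapply(dirs, function(d) {
      length(list.files(d, pattern = "\\.png$"))
    }, integer(1))
    names(counts) <- basename(dirs)
  } else {
    counts <- x
  }
  catalog <- morphologyCatalog()
  known <- names(counts) %in% catalog$class_name
  ord <- c(intersect(catalog$class_name, names(counts)),
           names(counts)[!known])
  counts <- counts[ord]
  total <- sum(counts)
  fam <- catalog$family[match(names(counts), catalog$class_name)]
  out <- data.frame(
    family = ifelse(is.na(fam), "Unlisted", fam),
    class_name = names(counts),
    count = as.integer(counts),
    percentage = if (total > 0) round(100 * counts / total, 2) else
      numeric(length(counts)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total") <- total
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}
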