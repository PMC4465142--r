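#' Write a DVH to the plain-text CSV dialect
#'
#' One structure per file. Comment header lines carry the metadata
#' (`# structure=`, `# technique=`, `# plan_type=`, `# prescription_Gy=`,
#' `# kind=differential|cumulative`, `# total_volume_cm3=`,
#' `# bin_width_Gy=` for differential histograms), followed by two columns
#' `dose_Gy,volume_fraction`. Doses are written with 6 decimals and volume
#' fractions with 9 (fractions spread over a thousand bins need the extra
#' digits to stay normalized on re-read); formatting is fixed, so the
#' writer is byte-stable.
#'
#' @param x A [structure_plan()], [dvh_differential()] or
#'   [dvh_cumulative()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(x, path) {
  meta <- character(0)
  label <- NULL
  if (inherits(x, "structure_plan")) {
    meta <- c(sprintf("# technique=%s", x$technique),
              sprintf("# plan_type=%s", x$plan_type),
              sprintf("# prescription_Gy=%.6f", x$prescription_dose))
    dvh <- x$dvh
    label <- x$organ
  } else dvh <- x
  if (is.null(label)) label <- dvh$structure_label
  if (inherits(dvh, "dvh_diff")) {
    kind <- "differential"
    dose <- dvh$bin_center
    vf <- dvh$volume_fraction
    extra <- sprintf("# bin_width_Gy=%.9f", dvh$bin_width)
  } else if (inherits(dvh, "dvh_cum")) {
    kind <- "cumulative"
    dose <- dvh$dose
    vf <- dvh$volume_fraction
    extra <- character(0)
  } else stop("x must be a structure_plan, dvh_diff or dvh_cum object")
  lines <- c(
    sprintf("# structure=%s", label),
    meta,
    sprintf("# kind=%s", kind),
    if (!is.null(dvh$total_volume))
      sprintf("# total_volume_cm3=%.6f", dvh$total_volume),
    extra,
    "dose_Gy,volume_fraction",
    sprintf("%.6f,%.9f", dose, vf))
  writeLines(lines, path)
  invisible(path)
}

#' Read a DVH from the CSV dialect
#'
#' Auto-detects differential vs cumulative form from the `# kind=` header
#' (falling back to the curve shape: monotone non-increasing with value 1
#' at the start reads as cumulative). If technique and plan type headers
#' are present the result is a full [structure_plan()]; otherwise the bare
#' DVH object is returned.
#'
#' @param path Input file path.
#' @return A [structure_plan()], [dvh_differential()] or
#'   [dvh_cumulative()] object.
#' @export
read_dvh <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such DVH file: %s", path))
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr_lines) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L || !grepl("^dose_Gy", body[1]))
    stop(sprintf("malformed DVH file (expected 'dose_Gy,volume_fraction' column header): %s", path))
  dat <- utils::read.csv(text = body, header = TRUE)
  dose <- dat[[1]]; vf <- dat[[2]]
  kind <- meta$kind
  if (is.null(kind)) {
    kind <- if (all(diff(vf) <= 1e-9) && abs(vf[1] - 1) < 1e-3)
      "cumulative" else "differential"
  }
  tv <- if (!is.null(meta$total_volume_cm3))
    as.numeric(meta$total_volume_cm3)
  label <- if (!is.null(meta$structure)) meta$structure else ""
  dvh <- if (kind == "differential") {
    bw <- if (!is.null(meta$bin_width_Gy)) as.numeric(meta$bin_width_Gy)
    else if (length(dose) > 1L) dose[2] - dose[1] else 0.05
    dvh_differential(dose, vf, bin_width = bw, total_volume = tv,
                     structure_label = label)
  } else {
    dvh_cumulative(dose, vf, total_volume = tv, structure_label = label)
  }
  if (!is.null(meta$technique) && !is.null(meta$plan_type)) {
    if (kind != "differential")
      dvh <- as_differential(dvh)
    rx <- if (!is.null(meta$prescription_Gy))
      as.numeric(meta$prescription_Gy) else 50
    return(structure_plan(label, meta$technique, meta$plan_type, dvh, rx))
  }
  dvh
}

#' Write a beam's-eye-view scene to CSV
#'
#' Header lines `# edge_point=x,y`, `# edge_normal=nx,ny` and optionally
#' `# field_bounds=xmin,xmax,ymin,ymax`, followed by `x_cm,y_cm` polygon
#' vertex rows.
#'
#' @param scene A [bev_scene()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "bev_scene"))
  lines <- c(
    sprintf("# edge_point=%.9f,%.9f", scene$edge_point[1], scene$edge_point[2]),
    sprintf("# edge_normal=%.9f,%.9f", scene$edge_normal[1],
            scene$edge_normal[2]),
    if (!is.null(scene$field_bounds))
      sprintf("# field_bounds=%.9f,%.9f,%.9f,%.9f", scene$field_bounds[1],
              scene$field_bounds[2], scene$field_bounds[3],
              scene$field_bounds[4]),
    "x_cm,y_cm",
    sprintf("%.9f,%.9f", scene$heart_contour[, 1], scene$heart_contour[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a beam's-eye-view scene from CSV
#'
#' @param path Input file path.
#' @return A [bev_scene()] object.
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such scene file: %s", path))
  lines <- readLines(path)
  grab <- function(key) {
    h <- grep(sprintf("^#\\s*%s=", key), lines, value = TRUE)
    if (length(h) == 0L) return(NULL)
    as.numeric(strsplit(sub(".*=", "", h[1]), ",")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  dat <- utils::read.csv(text = body, header = TRUE)
  bev_scene(as.matrix(dat), edge_point = grab("edge_point"),
            edge_normal = grab("edge_normal"),
            field_bounds = grab("field_bounds"))
}

#' Write a cohort to a directory of DVH/scene files plus a manifest
#'
#' One DVH CSV per (patient, organ, technique), one scene CSV per
#' (patient, technique) when geometry is present, and a `manifest.csv`
#' listing every file with its patient, organ (or `scene`), technique,
#' plan type and breathing amplitude.
#'
#' @param cohort List of [patient_plan_pair()] objects.
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output directory: %s", dir))
  rows <- list()
  for (pair in cohort) {
    for (tech in c("FB", "EIG")) {
      plans <- if (tech == "FB") pair$fb else pair$eig
      for (org in names(plans)) {
        fn <- sprintf("%s_%s_%s.csv", pair$patient_id, gsub("-", "", org),
                      tech)
        write_dvh(plans[[org]], file.path(dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pair$patient_id, plan_type = pair$plan_type,
          technique = tech, organ = org, file = fn,
          amplitude_mm = pair$amplitude_mm, stringsAsFactors = FALSE)
      }
      if (!is.null(pair$scenes) && !is.null(pair$scenes[[tech]])) {
        fn <- sprintf("%s_scene_%s.csv", pair$patient_id, tech)
        write_scene(pair$scenes[[tech]], file.path(dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pair$patient_id, plan_type = pair$plan_type,
          technique = tech, organ = "scene", file = fn,
          amplitude_mm = pair$amplitude_mm, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort_dir()]
#'
#' @param dir Directory containing `manifest.csv` and the listed files.
#' @return List of [patient_plan_pair()] objects.
#' @export
read_cohort_dir <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path))
    stop(sprintf("no manifest.csv in %s", dir))
  manifest <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  lapply(split(manifest, manifest$patient_id)[unique(manifest$patient_id)],
         function(mf) {
           plans <- list(FB = list(), EIG = list())
           scenes <- list()
           for (i in seq_len(nrow(mf))) {
             path <- file.path(dir, mf$file[i])
             if (mf$organ[i] == "scene") {
               scenes[[mf$technique[i]]] <- read_scene(path)
             } else {
               plans[[mf$technique[i]]][[mf$organ[i]]] <- read_dvh(path)
             }
           }
           patient_plan_pair(mf$patient_id[1], mf$plan_type[1],
                             fb = plans$FB, eig = plans$EIG,
                             scenes = if (length(scenes)) scenes,
                             amplitude_mm = mf$amplitude_mm[1])
         })
}
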