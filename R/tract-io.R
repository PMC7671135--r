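# Tract persistence: point CSV, per-tract JSON summaries, and legacy-VTK
# polydata polylines for external 3D viewers. All numeric output uses fixed
# formatting so identical runs produce byte-identical files.

fmt_num <- function(x, digits = 6) sprintf(paste0("%.", digits, "f"), x)

#' Export / import tract points as CSV
#'
#' Columns: `tract_id`, `point_index`, `x`, `y`, `z` (µm world coordinates).
#'
#' @param ts An [mt_tract_set()].
#' @param path Output file.
#' @return `path` invisibly; for the reader, an [mt_tract_set()] with
#'   lengths and directions recomputed from the points.
#' @export
write_tracts_csv <- function(ts, path) {
  stopifnot(inherits(ts, "mt_tract_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("tract_id,point_index,x,y,z", con)
  for (i in seq_along(ts$tracts)) {
    p <- ts$tracts[[i]]$points
    writeLines(sprintf("%d,%d,%s,%s,%s", i, seq_len(nrow(p)),
                       fmt_num(p[, 1]), fmt_num(p[, 2]), fmt_num(p[, 3])), con)
  }
  invisible(path)
}

#' @rdname write_tracts_csv
#' @param spacing Voxel spacing to record on the result, µm.
#' @export
read_tracts_csv <- function(path, spacing = NA_real_) {
  df <- read.csv(path)
  tracts <- lapply(split(df, df$tract_id), function(g) {
    g <- g[order(g$point_index), ]
    mt_tract(cbind(g$x, g$y, g$z))
  })
  mt_tract_set(unname(tracts[order(as.integer(names(tracts)))]),
               spacing = spacing)
}

#' Export / import per-tract JSON summaries
#'
#' One record per tract: curved length, chord length, mean direction,
#' point count.
#'
#' @inheritParams write_tracts_csv
#' @export
write_tracts_json <- function(ts, path) {
  stopifnot(inherits(ts, "mt_tract_set"))
  recs <- lapply(seq_along(ts$tracts), function(i) {
    tr <- ts$tracts[[i]]
    list(tract_id = i,
         curved_length = round(tr$curved_length, 6),
         chord_length = round(tr$chord_length, 6),
         mean_direction = round(tr$mean_direction, 9),
         n_points = nrow(tr$points))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tracts_json
#' @export
read_tracts_summary_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tibble(recs) |>
    tidyr_unpack_direction()
}

tidyr_unpack_direction <- function(df) {
  md <- do.call(rbind, df$mean_direction)
  df$mean_direction <- NULL
  df$dir_x <- md[, 1]; df$dir_y <- md[, 2]; df$dir_z <- md[, 3]
  as_tibble(df)
}

#' Export / import tracts as legacy VTK polydata
#'
#' ASCII VTK 2.0 polydata with one polyline per tract, for external 3D
#' viewers (ParaView and friends). Coordinates in µm.
#'
#' @inheritParams write_tracts_csv
#' @export
write_tracts_vtk <- function(ts, path) {
  stopifnot(inherits(ts, "mt_tract_set"))
  npts <- vapply(ts$tracts, function(t) nrow(t$points), integer(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               "fascicle tracts", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", sum(npts))), con)
  for (tr in ts$tracts) {
    p <- tr$points
    writeLines(sprintf("%s %s %s", fmt_num(p[, 1]), fmt_num(p[, 2]),
                       fmt_num(p[, 3])), con)
  }
  writeLines(sprintf("LINES %d %d", length(npts), sum(npts) + length(npts)),
             con)
  off <- c(0, cumsum(npts))
  for (i in seq_along(npts)) {
    ids <- seq(off[i], length.out = npts[i])
    writeLines(paste(c(npts[i], ids), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_tracts_vtk
#' @param spacing Voxel spacing to record on the result, µm.
#' @export
read_tracts_vtk <- function(path, spacing = NA_real_) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)[1]
  np <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  pts <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  il <- grep("^LINES ", lines)[1]
  nl <- as.integer(strsplit(lines[il], " ")[[1]][2])
  tracts <- vector("list", nl)
  for (i in seq_len(nl)) {
    ids <- scan(text = lines[il + i], quiet = TRUE)
    tracts[[i]] <- mt_tract(pts[ids[-1] + 1, , drop = FALSE])
  }
  mt_tract_set(tracts, spacing = spacing)
}

#' Export ground truth as JSON and CSV
#'
#' JSON carries the centerline polylines (µm); CSV has one row per fascicle
#' (direction, curved length, pennation).
#'
#' @param truth An `mt_ground_truth` from [generate_phantom()].
#' @param json_path,csv_path Output files (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(truth, "mt_ground_truth"))
  if (!is.null(json_path)) {
    obj <- list(tendon_axis = truth$tendon_axis,
                centerlines = lapply(truth$centerlines, function(m)
                  unname(round(m, 6))))
    jsonlite::write_json(obj, json_path, auto_unbox = FALSE, digits = NA)
  }
  if (!is.null(csv_path)) {
    df <- as.data.frame(truth$fascicles)
    for (cc in c("dir_x", "dir_y", "dir_z")) df[[cc]] <- fmt_num(df[[cc]], 9)
    for (cc in c("curved_length", "pennation")) df[[cc]] <- fmt_num(df[[cc]])
    write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(json_path, csv_path))
}
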