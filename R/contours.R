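# STDEV*COEFF contour fields and OpenDX export for overlay on the receptor
# structure in any molecular viewer.

#' STDEV*COEFF contour field
#'
#' Per grid point and field, the product of the PLS coefficient and the
#' descriptor standard deviation (computed on the matrix the model was fit
#' to). Columns dropped by the minimum-sigma filter contribute 0. Positive
#' steric values mark regions where bulk favours activity; positive
#' electrostatic values mark regions where positive probe interaction
#' (i.e. negative ligand charge nearby) favours activity.
#'
#' @param model a `pls_model` fit on `prep$X`.
#' @param prep the `field_prep` used for fitting (carries the retained-column
#'   mask and metadata).
#' @return A `contour_field`: list of 3D arrays (one per field), plus `grid`.
#' @export
stdev_coeff_field <- function(model, prep) {
  if (is.null(prep$col_meta)) stopf("prep lacks grid column metadata")
  sds <- apply(prep$X, 2, stats::sd)
  v_ret <- model$coefficients * sds
  v <- numeric(length(prep$retained))
  v[prep$retained] <- v_ret
  meta <- prep$col_meta
  grid <- attr(prep, "grid")
  fields <- unique(meta$field)
  arrays <- lapply(fields, function(f) {
    vals <- v[meta$field == f]
    vals
  })
  names(arrays) <- fields
  structure(list(values = arrays, col_meta = meta, grid = grid),
            class = "contour_field")
}

#' Contour isolevels
#'
#' Favoured level: the `favored_pct` percentile of the positive values;
#' disfavoured level: the `disfavored_pct` percentile of the negative
#' values (linear-interpolation percentile convention). A field with no
#' negative (or no positive) values reports `NA` for the missing level.
#'
#' @param values numeric vector of STDEV*COEFF values for one field.
#' @param favored_pct,disfavored_pct percentile levels.
#' @return list with `favored` and `disfavored` isolevels.
#' @export
contour_thresholds <- function(values, favored_pct = 80, disfavored_pct = 20) {
  pos <- values[values > 0]
  neg <- values[values < 0]
  list(
    favored = if (length(pos)) unname(stats::quantile(pos, favored_pct / 100)) else NA_real_,
    disfavored = if (length(neg)) unname(stats::quantile(neg, disfavored_pct / 100)) else NA_real_)
}

#' Export a scalar grid as OpenDX
#'
#' Writes the standard OpenDX regular-grid scalar format (readable by PyMOL,
#' VMD, Chimera) with values in lattice scan order (z fastest).
#'
#' @param values numeric vector (lattice scan order) or 3D array.
#' @param grid a `grid_region`.
#' @param path output `.dx` path.
#' @return `path`, invisibly.
#' @export
export_dx <- function(values, grid, path) {
  values <- as.numeric(values)
  nexp <- prod(grid$dims)
  if (length(values) != nexp) {
    stopf("value count %d does not match grid dims (%s = %d points)",
          length(values), paste(grid$dims, collapse = "x"), nexp)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            grid$dims[1], grid$dims[2], grid$dims[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            grid$dims[1], grid$dims[2], grid$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            nexp)), con)
  full <- c(values, rep(NA_real_, (3 - length(values) %% 3) %% 3))
  m <- matrix(sprintf("%.8g", full), ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(r[!grepl("NA", r)], collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Counterpart of [export_dx], used for round-trip checks and to re-import
#' exported maps.
#'
#' @param path a `.dx` file.
#' @return list with `values` and `grid` (a `grid_region`).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(sub(".*counts ", "", gp), "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^origin ", "", grep("^origin", lines, value = TRUE)[1]), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  d1 <- as.numeric(strsplit(sub("^delta ", "", deltas[1]), "\\s+")[[1]])
  spacing <- d1[d1 != 0][1]
  start <- grep("data follows", lines)[1] + 1L
  endmarks <- grep("^attribute|^object \"", lines)
  end <- min(endmarks[endmarks >= start]) - 1L
  values <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  grid <- structure(list(origin = org, spacing = spacing, dims = dims),
                    class = "grid_region")
  if (length(values) != prod(dims)) stopf("corrupt DX file: item count mismatch")
  list(values = values, grid = grid)
}

#' Export steric and electrostatic contour maps with a manifest
#'
#' Writes one `.dx` per field plus `manifest.json` recording the files, the
#' contour isolevels and (optionally) the receptor PDB to overlay them on.
#'
#' @param cf a `contour_field` from [stdev_coeff_field].
#' @param dir output directory (created if needed).
#' @param receptor_pdb optional path recorded in the manifest.
#' @param favored_pct,disfavored_pct percentile isolevels.
#' @return the manifest as a list, invisibly.
#' @export
export_contours <- function(cf, dir, receptor_pdb = NULL,
                            favored_pct = 80, disfavored_pct = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(receptor_pdb = receptor_pdb, maps = list())
  for (f in names(cf$values)) {
    path <- file.path(dir, paste0(f, ".dx"))
    export_dx(cf$values[[f]], cf$grid, path)
    th <- contour_thresholds(cf$values[[f]], favored_pct, disfavored_pct)
    manifest$maps[[f]] <- list(file = basename(path),
                               favored_level = th$favored,
                               disfavored_level = th$disfavored)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
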