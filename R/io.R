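# File I/O: STL (ASCII and binary) and OBJ bodies, CSV/JSON reports, YAML
# run configuration. Coordinates in files are always mm, right-handed, with
# no implicit unit scaling.

.file_ext <- function(path) tolower(tools::file_ext(path))

#' Read a body from an STL or OBJ file
#'
#' STL (binary or ASCII, auto-detected) and Wavefront OBJ are supported.
#' STL stores unshared per-facet vertices, so vertices are uniquified in
#' order of first appearance and faces re-indexed; OBJ preserves vertex
#' order exactly. Some exporters write OBJ files oriented "Forward: -Z,
#' Up: Y"; `orient = "y_forward_z_up"` undoes that convention on import by
#' mapping (x, y, z) to (x, -z, y). The default applies no permutation.
#'
#' @param path File path (`.stl` or `.obj`).
#' @param orient `"none"` or `"y_forward_z_up"`.
#' @param label Body label; defaults to the file name.
#' @return An `icr_body`.
#' @export
read_body <- function(path, orient = c("none", "y_forward_z_up"),
                      label = NULL) {
  orient <- match.arg(orient)
  if (!file.exists(path) || file.size(path) == 0) {
    abort(sprintf("File '%s' is missing or empty.", path),
          class = "icrlab_error_format")
  }
  ext <- .file_ext(path)
  parsed <- switch(ext,
    stl = .read_stl(path),
    obj = .read_obj(path),
    abort(sprintf("Unsupported body format '.%s' (use .stl or .obj).", ext),
          class = "icrlab_error_format")
  )
  m <- parsed$vertices
  if (orient == "y_forward_z_up") {
    m <- cbind(m[, 1L], -m[, 3L], m[, 2L])
  }
  body(m, faces = parsed$faces, label = label %||% basename(path))
}

.read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 facet count, 50 bytes per facet
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  is_binary <- FALSE
  if (sz >= 84) {
    nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(nfac) && nfac >= 0 && sz == 84 + 50 * as.numeric(nfac)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    tri <- matrix(NA_real_, nrow = 3L * nfac, ncol = 3L)
    for (i in seq_len(nfac)) {
      vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)  # attribute byte count
      tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], ncol = 3L,
                                              byrow = TRUE)
    }
    return(.unshare_triangles(tri, path))
  }
  close(con)
  on.exit()
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vx) == 0 || length(vx) %% 3 != 0) {
    abort(sprintf("'%s' is not a readable STL file (found %d vertex lines).",
                  path, length(vx)),
          class = "icrlab_error_format")
  }
  tri <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(v)) {
      abort(sprintf("Malformed vertex line in '%s': '%s'", path,
                    paste(p, collapse = " ")),
            class = "icrlab_error_format")
    }
    v
  }))
  .unshare_triangles(tri, path)
}

.unshare_triangles <- function(tri, path) {
  if (anyNA(tri)) {
    abort(sprintf("'%s' contains non-numeric vertex data.", path),
          class = "icrlab_error_format")
  }
  key <- paste(tri[, 1L], tri[, 2L], tri[, 3L], sep = "|")
  first <- !duplicated(key)
  verts <- tri[first, , drop = FALSE]
  index <- match(key, key[first])
  faces <- matrix(index, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0) {
    abort(sprintf("'%s' contains no vertex ('v') lines.", path),
          class = "icrlab_error_format")
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
  if (anyNA(verts)) {
    abort(sprintf("Malformed vertex line in '%s'.", path),
          class = "icrlab_error_format")
  }
  faces <- NULL
  if (length(flines) > 0) {
    faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
      function(p) as.integer(sub("/.*", "", p[2:4]))))
  }
  list(vertices = verts, faces = faces)
}

#' Write a body to STL or OBJ
#'
#' OBJ preserves vertex order and full double precision and is the
#' preferred round-trip format. STL requires triangle faces (it is a facet
#' soup); binary STL stores 32-bit floats, so coordinates are quantized to
#' single precision on write.
#'
#' @param body An `icr_body`.
#' @param path Output path; format chosen by extension (`.stl` / `.obj`).
#' @param ascii For STL: write the ASCII variant instead of binary.
#' @return `path`, invisibly.
#' @export
write_body <- function(body, path, ascii = FALSE) {
  .check_body(body)
  ext <- .file_ext(path)
  switch(ext,
    obj = .write_obj(body, path),
    stl = .write_stl(body, path, ascii = ascii),
    abort(sprintf("Unsupported body format '.%s' (use .stl or .obj).", ext),
          class = "icrlab_error_format")
  )
  invisible(path)
}

.write_obj <- function(body, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# icrlab body '%s' (mm, right-handed)",
                     body_label(body)), con)
  m <- body_matrix(body)
  writeLines(sprintf("v %.17g %.17g %.17g", m[, 1L], m[, 2L], m[, 3L]), con)
  f <- body_faces(body)
  if (!is.null(f)) {
    writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  }
}

.facet_data <- function(body) {
  f <- body_faces(body)
  if (is.null(f)) {
    abort("STL needs triangle faces; this body has none (write OBJ instead).",
          class = "icrlab_error_format")
  }
  m <- body_matrix(body)
  a <- m[f[, 1L], , drop = FALSE]
  b <- m[f[, 2L], , drop = FALSE]
  cc <- m[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-30] <- 1
  list(a = a, b = b, c = cc, normal = nrm / len)
}

.write_stl <- function(body, path, ascii = FALSE) {
  fd <- .facet_data(body)
  nfac <- nrow(fd$a)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", body_label(body)), con)
    for (i in seq_len(nfac)) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", fd$normal[i, 1L],
                fd$normal[i, 2L], fd$normal[i, 3L]),
        "    outer loop",
        sprintf("      vertex %.17g %.17g %.17g",
                c(fd$a[i, 1L], fd$b[i, 1L], fd$c[i, 1L]),
                c(fd$a[i, 2L], fd$b[i, 2L], fd$c[i, 2L]),
                c(fd$a[i, 3L], fd$b[i, 3L], fd$c[i, 3L])),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", body_label(body)), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("icrlab binary STL",
                                               body_label(body))))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nfac), con, size = 4L, endian = "little")
    for (i in seq_len(nfac)) {
      writeBin(c(fd$normal[i, ], fd$a[i, ], fd$b[i, ], fd$c[i, ]), con,
               size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
}

#' Write an experiment report
#'
#' Deterministic column order, full double precision, and a leading `#`
#' comment line embedding a hash of the report's provenance (column names
#' plus any `config` attribute), so a re-run can be compared byte for
#' byte.
#'
#' @param rows A data frame of homogeneous result records.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default from the extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = NULL) {
  if (!is.data.frame(rows)) {
    abort("`rows` must be a data frame.", class = "icrlab_error_parameter")
  }
  format <- format %||% .file_ext(path)
  if (!format %in% c("csv", "json")) {
    abort("`format` must be 'csv' or 'json'.", class = "icrlab_error_parameter")
  }
  hash <- rlang::hash(list(names(rows), attr(rows, "config")))
  plain <- as.data.frame(rows)[, names(rows), drop = FALSE]
  # list-columns (e.g. axes) cannot be serialized flat
  plain <- plain[, !vapply(plain, is.list, logical(1)), drop = FALSE]
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# icrlab report %s", hash), con)
    old <- options(digits = 15)
    on.exit(options(old), add = TRUE)
    write.csv(plain, con, row.names = FALSE)
  } else {
    jsonlite::write_json(list(meta = list(generator = "icrlab", hash = hash),
                              rows = plain),
                         path, digits = NA, auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report path (`.csv` or `.json`).
#' @return A tibble.
#' @export
read_report <- function(path) {
  ext <- .file_ext(path)
  if (ext == "json") {
    as_tibble(jsonlite::fromJSON(path)$rows)
  } else {
    as_tibble(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
  }
}

#' Run configuration
#'
#' A fully serializable description of one laboratory run: the body (a
#' synthetic arch spec or a mesh file), the axis, the transition grids, the
#' axis-error layout, the seed and the output directory. A run is
#' reproducible from its persisted configuration alone.
#'
#' @param seed Integer master seed.
#' @param body Either a list of [arch_spec()] arguments (field `type =
#'   "arch"`) or `list(type = "file", path = ...)`.
#' @param axis_offset Offset of the hinge axis from the body centroid, mm.
#' @param transition List with `alphas`, `magnitudes`, `directions`.
#' @param axis_error List with `set_alphas`, `shifts`, `rotations`, and
#'   [group_layout()] arguments under `layout`.
#' @param outdir Output directory for reports.
#' @return A list of class `icr_run_config`.
#' @export
run_config <- function(seed = 7,
                       body = list(type = "arch"),
                       axis_offset = c(0, 0, 40),
                       transition = list(),
                       axis_error = list(),
                       outdir = ".") {
  structure(list(seed = as.integer(seed), body = body,
                 axis_offset = as.numeric(axis_offset),
                 transition = transition, axis_error = axis_error,
                 outdir = outdir),
            class = "icr_run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "icr_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

# materialize the body described by a config
.config_body <- function(config) {
  b <- config$body
  if (identical(b$type, "file")) {
    read_body(b$path, orient = b$orient %||% "none")
  } else {
    args <- b[setdiff(names(b), "type")]
    if (is.null(args$seed)) args$seed <- config$seed
    generate_arch(do.call(arch_spec, args))
  }
}

#' Execute a configured run
#'
#' Materializes the body, runs the requested pipelines and writes CSV and
#' JSON reports (plus the persisted configuration) under `config$outdir`.
#'
#' @param config An [run_config()].
#' @param what Which pipelines to run.
#' @return Named list of result tibbles, invisibly.
#' @export
run_pipeline <- function(config, what = c("transition", "axis_error")) {
  stopifnot(inherits(config, "icr_run_config"))
  what <- match.arg(what, several.ok = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  b <- .config_body(config)
  axis <- default_hinge_axis(b, offset = config$axis_offset)
  out <- list()
  write_run_config(config, file.path(config$outdir, "run_config.yaml"))
  if ("transition" %in% what) {
    args <- c(list(body = b, axis = axis), config$transition)
    res <- do.call(run_transition_experiment, args)
    attr(res, "config") <- unclass(config)
    write_report(res, file.path(config$outdir, "transition.csv"))
    write_report(res, file.path(config$outdir, "transition.json"))
    out$transition <- res
  }
  if ("axis_error" %in% what) {
    layout_args <- config$axis_error$layout %||% list()
    groups <- build_groups(axis, b, do.call(group_layout, layout_args))
    args <- c(list(body = b, groups = groups),
              config$axis_error[setdiff(names(config$axis_error), "layout")])
    res <- do.call(run_axis_error_experiment, args)
    attr(res, "config") <- unclass(config)
    write_report(res, file.path(config$outdir, "axis_error.csv"))
    write_report(summarize_axis_error(res),
                 file.path(config$outdir, "axis_error_summary.csv"))
    out$axis_error <- res
  }
  invisible(out)
}
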