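# Persistent JSON project file: image references, VOI definitions, TACs,
# fit results, transforms, polar maps, and an append-only log of executed
# operations. Large voxel arrays stay in NIfTI sidecars referenced by
# path; everything numeric is written at full precision so reloading
# restores results bit-identically.

PROJECT_SCHEMA <- 1L

#' Create, save and load analysis projects
#'
#' A project records references to images on disk, VOI definitions, TACs,
#' kinetic fit results, rigid transforms, polar maps, and an append-only
#' operation log, in a human-diffable JSON file. Reloading restores every
#' stored result exactly; files with a newer schema version are rejected.
#'
#' @param name project name.
#' @return a `pet_project` object.
#' @export
project_new <- function(name = "untitled") {
  structure(list(schema = PROJECT_SCHEMA, name = name,
                 images = list(), vois = list(), tacs = list(),
                 fits = list(), transforms = list(), polar_maps = list(),
                 log = list()),
            class = "pet_project")
}

#' @rdname project_new
#' @param p a `pet_project`.
#' @param op operation name; `params` a named list of its parameters.
#' @param params named list.
#' @export
project_log <- function(p, op, params = list()) {
  p$log[[length(p$log) + 1]] <- list(op = op, params = params)
  p
}

#' @rdname project_new
#' @param key entry name.
#' @param path image path; `format` its format tag.
#' @param format format tag.
#' @export
project_add_image <- function(p, key, path, format = "nifti") {
  p$images[[key]] <- list(path = path, format = format)
  project_log(p, "add_image", list(key = key, path = path))
}

#' @rdname project_new
#' @param x the object to store (a [tac()], [rigid_transform()],
#'   [voi()], fit, or polar map depending on the function).
#' @export
project_add_tac <- function(p, key, x) {
  stopifnot(inherits(x, "tac"))
  p$tacs[[key]] <- list(mid_s = x$mid_s, dur_s = x$dur_s, value = x$value,
                        label = attr(x, "label") %||% "",
                        role = attr(x, "role"))
  project_log(p, "add_tac", list(key = key))
}

#' @rdname project_new
#' @export
project_add_transform <- function(p, key, x) {
  stopifnot(inherits(x, "rigid_transform"))
  p$transforms[[key]] <- list(rx = x$rx, ry = x$ry, rz = x$rz,
                              tx = x$tx, ty = x$ty, tz = x$tz,
                              center = x$center)
  project_log(p, "add_transform", list(key = key))
}

#' @rdname project_new
#' @export
project_add_fit <- function(p, key, x) {
  entry <- if (inherits(x, "compartment_fit")) {
    list(kind = "compartment", model = x$model,
         estimates = as.list(x$estimates), se = as.list(x$se),
         wrss = x$wrss, converged = x$converged)
  } else if (inherits(x, "graphical_fit")) {
    list(kind = "graphical", method = x$method, slope = x$slope,
         intercept = x$intercept, r_squared = x$r_squared,
         t_star = x$t_star, n = x$n)
  } else stop("unsupported fit object")
  p$fits[[key]] <- entry
  project_log(p, "add_fit", list(key = key))
}

#' @rdname project_new
#' @export
project_add_voi <- function(p, key, x) {
  stopifnot(inherits(x, "voi"))
  entry <- switch(x$type,
    mask = stop("mask VOIs are stored as NIfTI files; save the mask ",
                "with write_image() and register it with ",
                "project_add_image()"),
    roi_stack = list(type = "roi_stack", axis = x$axis, label = x$label,
                     rois = lapply(x$rois, function(r)
                       c(list(axis = r$axis, slice = r$slice,
                              label = r$label), r$shape))),
    ball = list(type = "ball", center = x$center, radius = x$radius,
                label = x$label),
    cylinder = list(type = "cylinder", base = x$base,
                    direction = x$direction, radius = x$radius,
                    length = x$length, label = x$label))
  p$vois[[key]] <- entry
  project_log(p, "add_voi", list(key = key))
}

#' @rdname project_new
#' @export
project_add_polar_map <- function(p, key, x) {
  p$polar_maps[[key]] <- list(values = unclass(x)[, , drop = FALSE],
                              geometry = attr(x, "geometry"),
                              stat = attr(x, "stat"))
  project_log(p, "add_polar_map", list(key = key))
}

#' @rdname project_new
#' @param path file path of the JSON project file.
#' @export
project_save <- function(p, path) {
  stopifnot(inherits(p, "pet_project"))
  # digits = I(17): significant-digit mode that round-trips IEEE doubles
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname project_new
#' @export
project_load <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (is.null(raw$schema) || raw$schema > PROJECT_SCHEMA)
    stop("project file has schema version ", raw$schema %||% "<missing>",
         "; this build reads versions up to ", PROJECT_SCHEMA)
  structure(raw, class = "pet_project")
}

#' Reconstruct a stored TAC / transform from a project
#' @param p a `pet_project`; `key` the entry name.
#' @param key entry name.
#' @return the restored object.
#' @export
project_get_tac <- function(p, key) {
  e <- p$tacs[[key]]
  if (is.null(e)) stop("no TAC '", key, "' in project")
  x <- tac(e$mid_s, e$dur_s, e$value, label = e$label)
  if (!is.null(e$role)) x <- input_function(x, e$role)
  x
}

#' @rdname project_get_tac
#' @export
project_get_transform <- function(p, key) {
  e <- p$transforms[[key]]
  if (is.null(e)) stop("no transform '", key, "' in project")
  rigid_transform(e$rx, e$ry, e$rz, e$tx, e$ty, e$tz, unlist(e$center))
}

#' @export
print.pet_project <- function(x, ...) {
  cat(sprintf("<pet_project> '%s' (schema %d)\n", x$name, x$schema))
  for (slot in c("images", "vois", "tacs", "fits", "transforms",
                 "polar_maps"))
    if (length(x[[slot]]))
      cat(sprintf("  %s: %s\n", slot,
                  paste(names(x[[slot]]), collapse = ", ")))
  cat(sprintf("  log: %d entries\n", length(x$log)))
  invisible(x)
}
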