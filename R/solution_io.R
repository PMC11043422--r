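# Solution files: canonical JSON mirroring the solution fields, with an
# embedded echo of the instance id and solve options for provenance.

mat_to_rows <- function(m) unname(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
arr_to_nested <- function(a) {
  d <- dim(a)
  unname(lapply(seq_len(d[1]), function(i)
    unname(lapply(seq_len(d[2]), function(j) unname(a[i, j, ])))))
}

#' Write a solution to its canonical JSON form
#'
#' @param sol a `bsc_solution`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, path) {
  opts <- sol$options
  doc <- list(
    collected_perm = mat_to_rows(sol$collected_perm),
    collected_temp = mat_to_rows(sol$collected_temp),
    deliver = arr_to_nested(sol$deliver),
    instance_id = sol$instance_id,
    inventory = mat_to_rows(sol$inventory),
    objective_cost = sol$objective_cost,
    objective_shortage_ratio = sol$objective_shortage_ratio,
    objective_shortage_units = sol$objective_shortage_units,
    open_center = as.list(sol$open_center),
    open_field = as.list(sol$open_field),
    open_perm = as.list(sol$open_perm),
    open_temp = as.list(sol$open_temp),
    options = list(
      formulation = opts$formulation,
      integral_vehicles = opts$integral_vehicles,
      mip_gap = opts$mip_gap,
      objective = opts$objective,
      solver_backend = opts$solver_backend,
      time_limit = if (is.finite(opts$time_limit)) opts$time_limit else NULL),
    scenario_id = sol$scenario_id,
    ship_perm = arr_to_nested(sol$ship_perm),
    ship_temp = arr_to_nested(sol$ship_temp),
    shortage = sol$shortage,
    sites = list(center = names(sol$open_center),
                 field = names(sol$open_field),
                 perm = names(sol$open_perm),
                 temp = names(sol$open_temp),
                 treat = dimnames(sol$deliver)[[2]]),
    solver_status = sol$solver_status
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a solution written by [write_solution()]
#'
#' @param path path to the solution JSON document.
#' @return a `bsc_solution` (without solver internals).
#' @export
read_solution <- function(path) {
  if (!file.exists(path)) stop("solution file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- lapply(doc$sites, function(v) as.character(unlist(v)))
  nT <- length(unlist(doc$shortage))
  rows_to_mat <- function(rows, rn) {
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
    if (is.null(m)) m <- matrix(numeric(0), 0, nT)
    rownames(m) <- rn
    m
  }
  nested_to_arr <- function(nst, d1, d2) {
    a <- array(0, c(length(d1), length(d2), nT), dimnames = list(d1, d2, NULL))
    for (i in seq_along(nst))
      for (j in seq_along(nst[[i]]))
        a[i, j, ] <- as.numeric(unlist(nst[[i]][[j]]))
    a
  }
  named_logical <- function(x) {
    stats::setNames(as.logical(unlist(x)), names(x))
  }
  o <- doc$options
  opts <- solve_options(
    objective = o$objective, mip_gap = o$mip_gap,
    time_limit = if (is.null(o$time_limit)) Inf else o$time_limit,
    integral_vehicles = isTRUE(o$integral_vehicles),
    solver_backend = o$solver_backend, formulation = o$formulation)
  structure(list(
    instance_id = doc$instance_id,
    scenario_id = doc$scenario_id,
    open_temp = named_logical(doc$open_temp),
    open_perm = named_logical(doc$open_perm),
    open_center = named_logical(doc$open_center),
    open_field = named_logical(doc$open_field),
    collected_temp = rows_to_mat(doc$collected_temp, ids$temp),
    collected_perm = rows_to_mat(doc$collected_perm, ids$perm),
    ship_temp = nested_to_arr(doc$ship_temp, ids$temp, ids$center),
    ship_perm = nested_to_arr(doc$ship_perm, ids$perm, ids$center),
    deliver = nested_to_arr(doc$deliver, ids$center, ids$treat),
    inventory = rows_to_mat(doc$inventory, ids$center),
    shortage = as.numeric(unlist(doc$shortage)),
    objective_cost = doc$objective_cost %||% NA_real_,
    objective_shortage_ratio = doc$objective_shortage_ratio %||% NA_real_,
    objective_shortage_units = doc$objective_shortage_units %||% NA_real_,
    solver_status = doc$solver_status,
    nodes = NA_integer_, infeasible_hint = NULL,
    options = opts
  ), class = "bsc_solution")
}
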