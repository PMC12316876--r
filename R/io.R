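#' Write a network to plain-text files
#'
#' Serializes the connection list (pre id, post id, class, delay ms,
#' weights, frozen flag) as CSV and the layout (cell coordinates,
#' population membership, pattern assignments) as JSON.
#'
#' @param net a `bcpnn_network`
#' @param edge_file CSV path for the edge list
#' @param layout_file optional JSON path for the layout (requires
#'   jsonlite)
#' @return the paths, invisibly
#' @export
write_network <- function(net, edge_file, layout_file = NULL) {
  co <- net$conns
  edges <- data.frame(pre = co$pre, post = co$post,
                      class = c("within", "associative", "pyr_basket",
                                "basket_pyr")[co$type + 1L],
                      delay_ms = co$delay,
                      w_ampa = if (is.null(co$w_ampa)) NA else co$w_ampa,
                      w_nmda = if (is.null(co$w_nmda)) NA else co$w_nmda,
                      frozen = if (is.null(co$frozen)) NA else co$frozen)
  utils::write.csv(edges, edge_file, row.names = FALSE)
  if (!is.null(layout_file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write the layout JSON")
    jsonlite::write_json(list(cells = net$cells,
                              patterns = net$patterns,
                              params = unclass(net$params),
                              seed = net$seed),
                         layout_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(edge_file, layout_file))
}

#' Write a task schedule to plain-text files
#'
#' The expanded, timed event table as CSV, with a human-readable block
#' summary appended as comment lines at the top.
#'
#' @param sched a `task_schedule`
#' @param file CSV path
#' @param stim a [stim_params()]
#' @return the path, invisibly
#' @export
write_schedule <- function(sched, file, stim = stim_params()) {
  ev <- schedule_events(sched, stim)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# variant: %s  seed: %d  arrangement: %d",
                     sched$variant, sched$seed, sched$arrangement), con)
  blocks <- table(sched$trials$block)
  writeLines(sprintf("# trials: %s",
                     paste(names(blocks), blocks, sep = "=",
                           collapse = ", ")), con)
  utils::write.csv(ev, con, row.names = FALSE)
  invisible(file)
}

#' Write an engine state snapshot to CSV
#'
#' One row per associative connection (probability traces, short-term
#' plasticity state and weights per component), plus a per-cell bias
#' table.
#'
#' @param snapshot a [snapshot_state()] result
#' @param assoc_file CSV path for the connection table
#' @param bias_file optional CSV path for the per-cell bias currents
#' @return the paths, invisibly
#' @export
write_snapshot <- function(snapshot, assoc_file, bias_file = NULL) {
  a <- snapshot$assoc
  a$time_ms <- snapshot$time_ms
  utils::write.csv(a, assoc_file, row.names = FALSE)
  if (!is.null(bias_file))
    utils::write.csv(data.frame(gid = seq_along(snapshot$bias) - 1L,
                                bias_pA = snapshot$bias,
                                time_ms = snapshot$time_ms),
                     bias_file, row.names = FALSE)
  invisible(c(assoc_file, bias_file))
}

#' Write spike rasters and results tables
#'
#' The raster is the two-column (time_ms, gid) convention with an
#' optional population-map sidecar (gid to network/HC/MC/pattern).
#'
#' @param session a `bcpnn_session` (run with `record_spikes = TRUE` for
#'   the raster)
#' @param net the network the session ran on
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return the written paths, invisibly
#' @export
write_session <- function(session, net, dir, prefix = "session") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  utils::write.csv(session$trials, p("trials.csv"), row.names = FALSE)
  paths <- c(paths, p("trials.csv"))
  if (!is.null(session$spikes)) {
    utils::write.csv(session$spikes, p("raster.csv"), row.names = FALSE)
    utils::write.csv(net$cells[, c("id", "network", "hc", "mc",
                                   "is_pyr", "pattern")],
                     p("population_map.csv"), row.names = FALSE)
    paths <- c(paths, p("raster.csv"), p("population_map.csv"))
  }
  if (!is.null(session$snapshot)) {
    write_snapshot(session$snapshot, p("snapshot_assoc.csv"),
                   p("snapshot_bias.csv"))
    paths <- c(paths, p("snapshot_assoc.csv"), p("snapshot_bias.csv"))
  }
  invisible(paths)
}
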