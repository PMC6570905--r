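#' Read / write trajectory tables
#'
#' Trajectory TSV dialect: columns `cell_id`, `t_min`, `fluorescence`
#' (linear scale), `division_flag` (0/1). `read_trajectories()` splits by
#' cell, checks uniform frame spacing, and returns log10 trajectories.
#'
#' @param path TSV file path.
#' @param dt expected frame spacing in minutes; inferred from the first
#'   cell when `NULL`.
#' @return List of [fluor_trajectory()].
#' @export
read_trajectories <- function(path, dt = NULL) {
  d <- read.delim(path, sep = "\t")
  need <- c("cell_id", "t_min", "fluorescence", "division_flag")
  if (!all(need %in% names(d)))
    stop("trajectory table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(d$fluorescence <= 0))
    stop("fluorescence values must be positive", call. = FALSE)
  by_cell <- split(d, d$cell_id)
  lapply(by_cell, function(g) {
    g <- g[order(g$t_min), ]
    step <- if (is.null(dt)) diff(g$t_min)[1] else dt
    fluor_trajectory(log10(g$fluorescence), dt = step,
                     cell_id = as.character(unique(g$cell_id)),
                     division = g$division_flag != 0,
                     t_min = g$t_min - g$t_min[1])
  })
}

#' @rdname read_trajectories
#' @param trajectories list of [fluor_trajectory()].
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr)
    data.frame(cell_id = tr$cell_id, t_min = tr$t_min,
               fluorescence = 10^tr$log10_fluor,
               division_flag = as.integer(tr$division)))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# metadata sidecar: resolved config + seed + version, enough to reproduce
write_metadata <- function(path, config, seed) {
  jsonlite::write_json(list(
    package = "autorep",
    version = as.character(packageVersion("autorep")),
    seed = seed, config = config,
    r_version = R.version.string), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  invisible(path)
}
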