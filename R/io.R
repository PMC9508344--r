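# Tabular time-series I/O: CSV and an STO/MOT-like tab-separated dialect
# (header with nRows/nColumns, time as the first column), plus JSON
# summaries of solved problems.

#' Write a time-series table in the STO-like dialect
#'
#' Tab-separated values preceded by a small header (`name`, `nRows=`,
#' `nColumns=`, `endheader`), with `time` as the first column.
#'
#' @param x data.frame or matrix with a `time` column first.
#' @param path output file path.
#' @param name table name recorded in the header.
#' @export
write_sto <- function(x, path, name = "series") {
  x <- as.data.frame(x)
  if (names(x)[1] != "time") stop("first column must be 'time'")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(x)),
               sprintf("nColumns=%d", ncol(x)),
               "endheader",
               paste(names(x), collapse = "\t")), con)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a time-series table in the STO-like dialect
#'
#' @param path input file path.
#' @return data.frame with the table; attribute `name` holds the header
#'   name.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "endheader")
  if (length(hdr_end) != 1) {
    stop("malformed STO header in ", path, ": no endheader line")
  }
  meta <- lines[seq_len(hdr_end - 1)]
  get_num <- function(key) {
    ln <- grep(paste0("^", key, "="), meta, value = TRUE)
    if (length(ln) != 1) stop("malformed STO header: missing ", key,
                              " (line ", hdr_end, ")")
    as.integer(sub(paste0("^", key, "="), "", ln))
  }
  nr <- get_num("nRows"); nc <- get_num("nColumns")
  cols <- strsplit(lines[hdr_end + 1], "\t")[[1]]
  if (length(cols) != nc) stop("malformed STO header: nColumns=", nc,
                               " but ", length(cols), " column names (line ",
                               hdr_end + 1, ")")
  body <- utils::read.table(text = lines[(hdr_end + 2):length(lines)],
                            sep = "\t", col.names = cols)
  if (nrow(body) != nr) stop("malformed STO body: nRows=", nr,
                             " but ", nrow(body), " data rows")
  attr(body, "name") <- meta[1]
  body
}

#' Write an experiment dataset to a directory
#'
#' Emits the coordinate, GRF and net-moment time series in the chosen
#' dialect plus a JSON metadata file (mass, stance windows, seed,
#' diagnostics).
#'
#' @param exp a `sprint_experiment`.
#' @param dir output directory (created if missing).
#' @param dialect "sto" (default) or "csv".
#' @return the directory, invisibly.
#' @export
write_experiment <- function(exp, dir, dialect = c("sto", "csv")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(tbl, stem) {
    if (dialect == "sto") write_sto(tbl, file.path(dir, paste0(stem, ".sto")), stem)
    else utils::write.csv(tbl, file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
  }
  emit(data.frame(time = exp$time, exp$q, check.names = FALSE), "coordinates")
  grf <- data.frame(time = exp$time,
                    r_ap = exp$grf$right[, "ap"], r_vertical = exp$grf$right[, "vertical"],
                    l_ap = exp$grf$left[, "ap"], l_vertical = exp$grf$left[, "vertical"])
  emit(grf, "grf")
  emit(data.frame(time = exp$time, exp$tau, check.names = FALSE), "moments")
  meta <- list(mass = exp$mass, stance = exp$stance,
               seed = exp$meta$seed, fs = exp$meta$fs,
               diagnostics = exp$meta$diagnostics)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an experiment dataset from a directory written by
#' [write_experiment()]
#'
#' @param dir directory path.
#' @param model optional `sprint_model` recorded into the metadata (needed
#'   downstream when the defaults do not apply).
#' @return a `sprint_experiment`.
#' @export
read_experiment <- function(dir, model = NULL) {
  read_any <- function(stem) {
    sto <- file.path(dir, paste0(stem, ".sto"))
    csv <- file.path(dir, paste0(stem, ".csv"))
    if (file.exists(sto)) read_sto(sto) else utils::read.csv(csv, check.names = FALSE)
  }
  qd <- read_any("coordinates")
  gd <- read_any("grf")
  td <- read_any("moments")
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  q <- as.matrix(qd[, -1]); colnames(q) <- names(qd)[-1]
  tau <- as.matrix(td[, -1]); colnames(tau) <- names(td)[-1]
  grf <- list(right = cbind(ap = gd$r_ap, vertical = gd$r_vertical),
              left = cbind(ap = gd$l_ap, vertical = gd$l_vertical))
  sprint_experiment(time = qd$time, q = q, grf = grf, tau = tau,
                    mass = meta$mass,
                    stance = list(right = unlist(meta$stance$right),
                                  left = unlist(meta$stance$left)),
                    meta = c(meta[c("seed", "fs")],
                             list(model = model, diagnostics = meta$diagnostics)))
}

#' Write an OCP solution to a directory
#'
#' State and control trajectories in the tabular dialect plus a JSON summary
#' with the solver status, the objective breakdown and, for tracking
#' solutions, the RMSD report.
#'
#' @param x a `sprint_tracking` or `sprint_predictive`.
#' @param dir output directory.
#' @param dialect "sto" or "csv".
#' @return the directory, invisibly.
#' @export
write_solution <- function(x, dir, dialect = c("sto", "csv")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sol <- x$sol
  model <- x$model
  g <- solution_grid(sol)
  states <- data.frame(time = g$t, g$X)
  names(states) <- c("time", model$dof_names, paste0("d_", model$dof_names))
  ctrl_t <- (seq_len(nrow(sol$U)) - 1) / sol$layout$N * sol$tf
  controls <- data.frame(time = ctrl_t, sol$U)
  cl <- control_layout(model)
  names(controls) <- c("time",
                       paste0("act_", model$internal_dofs),
                       paste0("res_", model$internal_dofs),
                       paste0("vdot_", model$dof_names),
                       paste0("grf_fx_", model$spheres$name),
                       paste0("grf_fy_", model$spheres$name))
  emit <- function(tbl, stem) {
    if (dialect == "sto") write_sto(tbl, file.path(dir, paste0(stem, ".sto")), stem)
    else utils::write.csv(tbl, file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
  }
  emit(states, "states")
  emit(controls, "controls")
  summ <- list(status = sol$status, objective = sol$objective,
               breakdown = as.list(sol$breakdown), tf = sol$tf,
               iterations = sol$iterations, kkt_error = sol$kkt_error,
               config = if (!is.null(x$config)) x$config else "tracking",
               rmsd = if (!is.null(x$rmsd)) lapply(x$rmsd, as.list) else NULL)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
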