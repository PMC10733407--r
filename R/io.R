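# Plain-text I/O: multi-frame XYZ with `rc=<value> frame=<idx>` comment
# lines, a minimal single-model PDB export (ions as HETATM), key-value run
# configuration files, and TSV tables with `#` metadata headers.

.pdb_atom_name <- c(BPA_O2p = "O2N", Gp1_P = "P", G1_O3p = "O3L",
                    H2p = "H2P", OSp = "OSP", ORp = "ORP", M1 = "MG1",
                    M2 = "MG2", K1 = "K1", G52_O = "O52", A59_O = "O59",
                    G60_O = "O60", U80_O = "O80", G78_O = "O78")

#' Write a model or trajectory as (multi-frame) XYZ
#'
#' Each frame's comment line is `rc=<value> frame=<idx>`.
#'
#' @param x An `active_site_model` or `bm_trajectory`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (inherits(x, "active_site_model")) {
    a <- x$atoms
    writeLines(as.character(nrow(a)), con)
    d1 <- model_distance(x, "BPA_O2p", "Gp1_P")
    d2 <- model_distance(x, "G1_O3p", "Gp1_P")
    writeLines(sprintf("rc=%.6f frame=1", d2 - d1), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f",
                       a$element, a$x, a$y, a$z), con)
  } else {
    nf <- n_frames(x)
    na <- length(x$labels)
    el <- if (!is.null(x$elements)) x$elements else x$labels
    for (f in seq_len(nf)) {
      writeLines(as.character(na), con)
      writeLines(sprintf("rc=%.6f frame=%d", x$rc[f], f), con)
      writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", el,
                         x$coords[f, , 1], x$coords[f, , 2],
                         x$coords[f, , 3]), con)
    }
  }
  invisible(file)
}

#' Read a multi-frame XYZ trajectory
#'
#' Parses the `rc=` comment convention; atom labels are taken from the
#' element column (supply `labels` to restore role labels).
#'
#' @param file Path.
#' @param labels Optional role labels (one per atom).
#' @return A `bm_trajectory`.
#' @export
read_xyz <- function(file, labels = NULL) {
  lines <- readLines(file)
  pos <- 1L
  frames <- list(); rcs <- numeric(0); el <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- as.integer(trimws(lines[pos]))
    comment <- lines[pos + 1L]
    rc <- NA_real_
    m <- regmatches(comment, regexec("rc=([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 2) rc <- as.numeric(m[2])
    body <- lines[(pos + 2L):(pos + 1L + na)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    el <- vapply(tok, `[`, character(1), 1)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    rcs <- c(rcs, rc)
    pos <- pos + 2L + na
  }
  nf <- length(frames)
  na <- nrow(frames[[1]])
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  structure(list(coords = coords,
                 labels = if (is.null(labels)) el else labels,
                 elements = el, rc = rcs, lambda = NULL, dt = NA_real_,
                 stride = 1L, xi_target = NA_real_),
            class = "bm_trajectory")
}

#' Write a single-model PDB snapshot
#'
#' Metal ions are written as HETATM records; role labels are mapped to
#' four-character atom names.
#'
#' @param model An `active_site_model`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(model, file) {
  a <- model$atoms
  ishet <- a$element %in% c("Mg", "K", "Li")
  rec <- ifelse(ishet, "HETATM", "ATOM  ")
  nm <- .pdb_atom_name[a$role]
  nm[is.na(nm)] <- substr(a$role[is.na(nm)], 1, 4)
  lines <- sprintf("%s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), nm, "ASM", 1L,
                   a$x, a$y, a$z, 1.00, 0.00, toupper(a$element))
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Run configuration
#'
#' Plain-text key-value configuration for a full pipeline run; round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param ion_type `"K"` or `"Li"`.
#' @param seed Master seed.
#' @param n_seeds Number of independent replicate schedules.
#' @param grid_lo,grid_hi,grid_step Reaction-coordinate grid (A).
#' @param window_ps,equil_ps Window and equilibration length (ps).
#' @param extended_ps,extended_equil_ps Extended-window lengths (ps).
#' @param growth_rate Drag rate (A/fs).
#' @param timestep Timestep (fs).
#' @param temperature Temperature (K).
#' @param friction Langevin friction (1/fs).
#' @param se_mode SE estimator mode.
#' @param correction Metric-correction mode (`"apply"`, `"report"`,
#'   `"off"`).
#' @param hb_max_dist,hb_max_angle_dev H-bond criteria.
#' @param pt_dwell Proton-transfer dwell window (frames).
#' @param out_dir Output directory.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(ion_type = "K", seed = 1, n_seeds = 3,
                       grid_lo = -1.4, grid_hi = 1.6, grid_step = 0.2,
                       window_ps = 5, equil_ps = 2, extended_ps = 7,
                       extended_equil_ps = 4, growth_rate = 0.003,
                       timestep = 0.5, temperature = 300, friction = 0.01,
                       se_mode = "autocorr", correction = "apply",
                       hb_max_dist = 2.2, hb_max_angle_dev = 50,
                       pt_dwell = 10, out_dir = "results") {
  cfg <- as.list(environment())
  if (timestep <= 0 || window_ps <= 0 || grid_step <= 0 ||
      growth_rate <= 0 || temperature <= 0)
    stop("schedule parameters must be positive")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param file Path.
#' @export
write_run_config <- function(config, file) {
  lines <- c("# bluemoonti run configuration",
             vapply(names(config), function(k) {
               v <- config[[k]]
               sprintf("%s = %s", k, paste(format(v, digits = 15),
                                           collapse = ","))
             }, character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines,
                   regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$",
                           lines))
  cfg <- list()
  for (m in kv) {
    if (length(m) != 3) next
    val <- strsplit(trimws(m[3]), ",")[[1]]
    suppressWarnings(num <- as.numeric(val))
    cfg[[m[2]]] <- if (all(!is.na(num))) num else val
  }
  structure(cfg, class = "run_config")
}

#' Reaction-coordinate grid of a config
#' @param config A `run_config`.
#' @return Numeric grid.
#' @export
config_grid <- function(config)
  seq(config$grid_lo, config$grid_hi, by = config$grid_step)

#' Hash of a configuration
#'
#' @param config A `run_config`.
#' @return Character md5 hash of the serialised key-value text.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Write a TSV table with `#` metadata header
#'
#' @param df Data frame.
#' @param file Path.
#' @param meta Named character vector written as `# key: value` lines.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, file, meta = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV table written by [write_tsv()]
#'
#' @param file Path.
#' @return Data frame; header metadata in attribute `meta`.
#' @export
read_tsv <- function(file) {
  lines <- readLines(file)
  metaln <- grep("^#", lines)
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), metaln)],
                          sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- sub("^# ", "", lines[metaln])
  df
}

#' Write / read reactive-surface parameters as key-value text
#'
#' One parameter per line (`key = value`, `#` comments); vectors are
#' comma-separated. Round-trips losslessly at full double precision.
#'
#' @param params A `pes_params`.
#' @param file Path.
#' @return The path ([write_pes_params()]) or a `pes_params`
#'   ([read_pes_params()]), invisibly for the writer.
#' @export
write_pes_params <- function(params, file) {
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  lines <- c("# reactive-surface parameters",
             sprintf("n_basins = %d", nrow(params$basins)))
  for (cl in c("depth", "xi_c", "s_c", "w_xi", "w_s"))
    lines <- c(lines, sprintf("basin_%s = %s", cl, num(params$basins[[cl]])))
  for (cl in c("wall_a", "wall_r0", "confine_k", "confine_d",
               "restraint_k", "temperature"))
    lines <- c(lines, sprintf("%s = %s", cl, num(params[[cl]])))
  if (!is.null(params$shape)) {
    lines <- c(lines,
               sprintf("shape_x0 = %s", num(params$shape$x0)),
               sprintf("shape_h = %s", num(params$shape$h)),
               sprintf("shape_value = %s", num(params$shape$value)),
               sprintf("shape_deriv = %s", num(params$shape$deriv)))
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_pes_params
#' @export
read_pes_params <- function(file) {
  cfg <- read_run_config(file)
  basins <- data.frame(depth = cfg$basin_depth, xi_c = cfg$basin_xi_c,
                       s_c = cfg$basin_s_c, w_xi = cfg$basin_w_xi,
                       w_s = cfg$basin_w_s)
  shape <- NULL
  if (!is.null(cfg$shape_value))
    shape <- list(x0 = cfg$shape_x0, h = cfg$shape_h,
                  value = cfg$shape_value, deriv = cfg$shape_deriv)
  pes_params(basins, shape = shape, wall_a = cfg$wall_a,
             wall_r0 = cfg$wall_r0, confine_k = cfg$confine_k,
             confine_d = cfg$confine_d, restraint_k = cfg$restraint_k,
             temperature = cfg$temperature)
}
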