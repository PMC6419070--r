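#' Write a trajectory to plain-text files
#'
#' Writes `<basename>_extension.csv` (sample index, time in ps, axial
#' extension in nm at full double precision), `<basename>_meta.json`
#' (seed, integrator parameters, chain, geometry, force and package
#' version - enough to re-run the producing command), and, when frames were
#' recorded, `<basename>_frames.xyz` in plain XYZ format.
#'
#' @param traj [run_trajectory()] result
#' @param basename path prefix for the output files
#' @return invisibly, the files written
#' @export
write_trajectory <- function(traj, basename) {
  stopifnot(inherits(traj, "wlc_trajectory"))
  dir.create(dirname(basename), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  csv <- paste0(basename, "_extension.csv")
  n <- length(traj$extension)
  df <- data.frame(sample = seq_len(n),
                   time_ps = seq_len(n) * traj$dt_sample,
                   extension_nm = traj$extension)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   csv, row.names = FALSE, quote = FALSE)
  files <- c(files, csv)

  meta <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("wlctube")),
    seed = traj$seed,
    dt_sample_ps = traj$dt_sample,
    L_nm = traj$L,
    chain = traj$chain,
    geometry = if (is.null(traj$geom)) NULL else
      list(Hh = traj$geom$Hh, Hw = traj$geom$Hw, kind = traj$geom$kind),
    force = traj$force,
    params = traj$params[c("dt", "steps", "temperature", "viscosity",
                           "hydrodynamics", "thin", "frame_every")],
    diagnostics = traj$diagnostics,
    n_samples = n
  )
  js <- paste0(basename, "_meta.json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, js)

  if (!is.null(traj$frames)) {
    xyz <- paste0(basename, "_frames.xyz")
    files <- c(files, write_xyz(traj$frames, xyz))
  }
  invisible(files)
}

## XYZ frame writer: array N x 3 x nframes
write_xyz <- function(frames, path, element = "C") {
  stopifnot(length(dim(frames)) == 3L)
  N <- dim(frames)[1]
  nf <- dim(frames)[3]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(N), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", element,
                       frames[, 1, f], frames[, 2, f], frames[, 3, f]), con)
  }
  path
}

#' Read XYZ frames
#'
#' @param path XYZ file
#' @return array `N x 3 x nframes`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop_parse(sprintf("%s:%d: expected an atom count", path, i))
    N <- as.integer(lines[i])
    if (i + 1L + N > length(lines))
      stop_parse(sprintf("%s:%d: truncated frame (need %d atom lines)",
                         path, i, N))
    block <- lines[(i + 2L):(i + 1L + N)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(bad))
      stop_parse(sprintf("%s:%d: malformed atom line", path, i + 1L + bad[1L]))
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop_parse(sprintf("%s: non-numeric coordinates in frame starting at line %d",
                         path, i))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + N
  }
  if (!length(frames)) stop_parse(sprintf("%s: no frames found", path))
  array(unlist(frames), dim = c(nrow(frames[[1L]]), 3, length(frames)))
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param basename the path prefix used when writing
#' @return object of class `wlc_trajectory` (without the live parameter
#'   objects; the metadata list is attached as `meta`)
#' @export
read_trajectory <- function(basename) {
  csv <- paste0(basename, "_extension.csv")
  js <- paste0(basename, "_meta.json")
  if (!file.exists(csv)) stop_parse(paste0("missing file: ", csv))
  if (!file.exists(js)) stop_parse(paste0("missing file: ", js))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  df <- tryCatch(utils::read.csv(csv), warning = function(w)
    stop_parse(sprintf("%s: malformed CSV (%s)", csv, conditionMessage(w))))
  need <- c("sample", "time_ps", "extension_nm")
  if (!all(need %in% names(df)))
    stop_parse(sprintf("%s:1: expected columns %s", csv,
                       paste(need, collapse = ", ")))
  if (anyNA(df$extension_nm))
    stop_parse(sprintf("%s:%d: non-numeric extension value", csv,
                       which(is.na(df$extension_nm))[1L] + 1L))
  if (!is.null(meta$n_samples) && nrow(df) != meta$n_samples)
    stop_parse(sprintf("%s: %d samples but metadata records %d (truncated?)",
                       csv, nrow(df), meta$n_samples))
  frames <- NULL
  xyz <- paste0(basename, "_frames.xyz")
  if (file.exists(xyz)) frames <- read_xyz(xyz)
  structure(list(extension = df$extension_nm,
                 dt_sample = meta$dt_sample_ps,
                 L = meta$L_nm,
                 seed = meta$seed,
                 params = meta$params,
                 chain = meta$chain,
                 geom = if (is.null(meta$geometry)) NULL else
                   channel_geometry(meta$geometry$Hh, meta$geometry$Hw,
                                    kind = meta$geometry$kind),
                 force = meta$force,
                 frames = frames,
                 final_positions = NULL,
                 diagnostics = meta$diagnostics,
                 meta = meta),
            class = "wlc_trajectory")
}
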