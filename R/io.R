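parse_config_value <- function(x) {
  x <- trimws(x)
  if (toupper(x) %in% c("TRUE", "FALSE")) return(as.logical(toupper(x)))
  if (toupper(x) %in% c("NA", "NONE")) return(NA_real_)
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) return(n)
  gsub('^"|"$', "", x)
}

#' Read a run configuration file
#'
#' Plain-text `key = value` format with `#` comments and optional
#' `[scenario]` section. Keys outside any section (or in `[params]`) must be
#' model parameter names; missing parameters are filled with the reference
#' defaults and the returned parameter list is fully resolved. Unknown keys
#' raise an error naming the key.
#'
#' @param path file path
#' @return list with `params` (validated parameter list) and `scenario`
#'   (named list of scenario keys, possibly empty)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  section <- "params"
  params <- list(); scenario <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% c("params", "scenario"))
        stop("unknown config section: [", section, "]")
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: '", ln, "'")
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- parse_config_value(paste(kv[-1], collapse = "="))
    if (section == "params") params[[key]] <- val else scenario[[key]] <- val
  }
  if ("beads_per_filament" %in% names(params))
    params$beads_per_filament <- as.integer(params$beads_per_filament)
  if ("monomers_per_segment" %in% names(params))
    params$monomers_per_segment <- as.integer(params$monomers_per_segment)
  p <- do.call(default_parameters, params)
  list(params = p, scenario = scenario)
}

#' Write a configuration file
#'
#' Inverse of [read_config()]: writes every parameter (and scenario entry)
#' as `key = value` lines, so `read_config(write_config(cfg))` round-trips.
#'
#' @param config list with `params` and optionally `scenario`
#' @param path output path
#' @return `path` invisibly
#' @export
write_config <- function(config, path) {
  p <- config$params
  fmt <- function(v) {
    if (is.na(v)) "NA"
    else if (is.logical(v)) as.character(v)
    else if (is.numeric(v)) as.character(v)
    else as.character(v)
  }
  skip <- c("zeta_b", "fa_radius", "fa_x0", "fa_x1", "fa_y0", "fa_y1")
  keys <- setdiff(names(p), skip)
  out <- c("[params]",
           vapply(keys, function(k) paste(k, "=", fmt(p[[k]])), character(1)))
  if (length(config$scenario)) {
    out <- c(out, "", "[scenario]",
             vapply(names(config$scenario),
                    function(k) paste(k, "=", fmt(config$scenario[[k]])),
                    character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Print the reference parameter values
#'
#' Emits the reference parameter set as config-format text, one `key = value`
#' line per parameter.
#'
#' @param con connection or "" for stdout
#' @export
print_defaults <- function(con = stdout()) {
  write_config(list(params = default_parameters()), con)
}

#' Write a frame as CSV tables
#'
#' Writes `<stem>_beads.csv` (uid, filament, index, positions, unwrapped x,
#' bound flag, birth time), `<stem>_bonds.csv` and `<stem>_crosslinks.csv`.
#'
#' @param state a `network_state`
#' @param stem output path stem
#' @return paths invisibly
#' @export
write_frame_csv <- function(state, stem) {
  paths <- paste0(stem, c("_beads.csv", "_bonds.csv", "_crosslinks.csv"))
  utils::write.csv(bead_table(state), paths[1], row.names = FALSE)
  bonds <- do.call(rbind, lapply(seq_along(state$fil_beads), function(f) {
    b <- state$fil_beads[[f]]
    if (length(b) < 2) return(NULL)
    data.frame(filament = state$fil_ids[f], i = b[-length(b)], j = b[-1],
               tau = state$fil_taus[[f]])
  }))
  if (is.null(bonds))
    bonds <- data.frame(filament = integer(0), i = integer(0),
                        j = integer(0), tau = numeric(0))
  utils::write.csv(bonds, paths[2], row.names = FALSE)
  xl <- as.data.frame(state$xl)
  utils::write.csv(xl, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write an XYZ snapshot
#'
#' One pseudo-atom per bead for external viewers; the species codes the
#' bead's situation: `A` plain actin, `B` adhesion-bound, `X` crosslinked.
#'
#' @param state a `network_state`
#' @param path output path
#' @param append append as an additional frame
#' @return `path` invisibly
#' @export
write_xyz <- function(state, path, append = FALSE) {
  n <- nrow(state$pos)
  species <- rep("A", n)
  if (nrow(state$xl)) species[unique(c(state$xl[, 1], state$xl[, 2]))] <- "X"
  species[state$bound == 1] <- "B"
  lines <- c(as.character(n),
             paste0("t=", format(state$t)),
             sprintf("%s %.6f %.6f %.6f", species,
                     state$pos[, 1], state$pos[, 2], state$pos[, 3]))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

CHECKPOINT_VERSION <- 1L

#' Save a checkpoint
#'
#' Serializes the full network state, its parameters and the current R RNG
#' state, so that [restore_checkpoint()] continues the trajectory
#' bit-identically to an uninterrupted run. The payload checksum is verified
#' on load.
#'
#' @param state a `network_state`
#' @param path output path
#' @return `path` invisibly
#' @export
write_checkpoint <- function(state, path) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  payload <- list(state = unclass(state),
                  rng = get(".Random.seed", envir = globalenv()))
  chk <- sum(as.numeric(state$pos)) + nrow(state$pos) + state$t
  obj <- list(version = CHECKPOINT_VERSION, checksum = chk, payload = payload)
  saveRDS(obj, path)
  invisible(path)
}

#' Restore a checkpoint
#'
#' @param path checkpoint path from [write_checkpoint()]
#' @return the saved `network_state`; the global RNG state is restored as a
#'   side effect
#' @export
restore_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable checkpoint: ", path))
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("checkpoint version mismatch: found ", obj$version,
         ", expected ", CHECKPOINT_VERSION)
  state <- obj$payload$state
  chk <- sum(as.numeric(state$pos)) + nrow(state$pos) + state$t
  if (!isTRUE(all.equal(chk, obj$checksum)))
    stop("checkpoint checksum mismatch: ", path)
  assign(".Random.seed", obj$payload$rng, envir = globalenv())
  class(state) <- "network_state"
  state
}
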