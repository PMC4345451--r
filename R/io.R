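# CSV / YAML interchange. All writers emit RFC-4180 CSV via write.csv
# with documented headers; all times are seconds unless a time unit
# rescaling is requested at ingest.

#' Read a visits CSV into an observation stream
#'
#' Accepts either `id,location,time_block` (integer blocks) or
#' `id,location,timestamp` (seconds, or ISO-8601 datetimes, binned into
#' `block_seconds` windows).
#'
#' @param path CSV path.
#' @param block_seconds Width of the sampling window used to bin
#'   timestamps (default 15 s).
#' @return An [observation_stream()].
#' @export
read_visits_csv <- function(path, block_seconds = mnbda_defaults()$block_seconds) {
  df <- read_checked(path, c("id", "location"))
  if ("time_block" %in% names(df)) {
    observation_stream(df$id, df$location, df$time_block)
  } else if ("timestamp" %in% names(df)) {
    ts <- df$timestamp
    secs <- if (is.numeric(ts)) ts else as.numeric(as.POSIXct(ts, tz = "UTC"))
    if (any(is.na(secs)))
      stop("unparseable timestamp in ", path, " (row ",
           which(is.na(secs))[1], ", column 'timestamp')", call. = FALSE)
    observation_stream(df$id, df$location, floor(secs / block_seconds))
  } else {
    stop(path, ": need a 'time_block' or 'timestamp' column", call. = FALSE)
  }
}

#' Write / read a square adjacency CSV
#'
#' Canonical network format: a header row of ids and an `id` first
#' column, weights in the body.
#'
#' @param net An [association_network()].
#' @param path CSV path.
#' @return `read_adjacency_csv` returns an [association_network()]
#'   (without observation counts); `write_adjacency_csv` returns `path`
#'   invisibly.
#' @export
write_adjacency_csv <- function(net, path) {
  df <- data.frame(id = net$node_ids, net$weights, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path) {
  df <- read_checked(path, "id")
  ids <- as.character(df$id)
  W <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(W), ids))
    stop(path, ": header ids must match the 'id' column in order", call. = FALSE)
  storage.mode(W) <- "double"
  association_network(W, node_ids = ids)
}

#' Write a network as an edge list
#'
#' Rows `id_a,id_b,weight`, only positive weights, with `id_a < id_b`
#' lexicographically.
#'
#' @param net An [association_network()].
#' @param path CSV path.
#' @export
write_edgelist_csv <- function(net, path) {
  W <- net$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  a <- net$node_ids[idx[, 1]]; b <- net$node_ids[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(id_a = a, id_b = b, weight = W[idx], stringsAsFactors = FALSE)
  df <- df[order(df$id_a, df$id_b), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write diffusion trials
#'
#' Arrival rows live in a diffusions CSV `trial,site,id,arrival_s`
#' (blank `arrival_s` = censored; `arrival_s = 0` = seeded demonstrator,
#' informed at the start); per-trial metadata in a trials CSV
#' `trial,site,t_end_s,tie_window_s`.
#'
#' @param diffusions_path,trials_path CSV paths.
#' @return `read_diffusions_csv` returns a list of [diffusion_data()].
#' @export
read_diffusions_csv <- function(diffusions_path, trials_path) {
  arr <- read_checked(diffusions_path, c("trial", "id", "arrival_s"))
  meta <- read_checked(trials_path, c("trial", "t_end_s"))
  if (!"tie_window_s" %in% names(meta)) meta$tie_window_s <- mnbda_defaults()$tie_window_s
  if (!"site" %in% names(meta)) meta$site <- "site1"
  lapply(seq_len(nrow(meta)), function(r) {
    tr <- as.character(meta$trial[r])
    rows <- arr[as.character(arr$trial) == tr & !is.na(arr$arrival_s) &
                  arr$arrival_s != "", , drop = FALSE]
    at <- as.numeric(rows$arrival_s)
    diffusion_data(trial_id = tr,
                   arrivals = setNames(at[at > 0], as.character(rows$id)[at > 0]),
                   seeded = as.character(rows$id)[at == 0],
                   t_end = as.numeric(meta$t_end_s[r]), site = as.character(meta$site[r]),
                   tie_window = as.numeric(meta$tie_window_s[r]))
  })
}

#' @param diffusions List of [diffusion_data()].
#' @rdname read_diffusions_csv
#' @export
write_diffusions_csv <- function(diffusions, diffusions_path, trials_path) {
  arr <- do.call(rbind, lapply(diffusions, function(d) {
    ids <- c(d$seeded, names(d$arrivals))
    if (length(ids) == 0)
      return(data.frame(trial = character(), site = character(), id = character(),
                        arrival_s = numeric(), stringsAsFactors = FALSE))
    data.frame(trial = d$trial_id, site = d$site, id = ids,
               arrival_s = c(rep(0, length(d$seeded)), unname(d$arrivals)),
               stringsAsFactors = FALSE)
  }))
  write.csv(arr, diffusions_path, row.names = FALSE)
  meta <- do.call(rbind, lapply(diffusions, function(d)
    data.frame(trial = d$trial_id, site = d$site, t_end_s = d$t_end,
               tie_window_s = d$tie_window, stringsAsFactors = FALSE)))
  write.csv(meta, trials_path, row.names = FALSE)
  invisible(diffusions_path)
}

#' Read a covariate table
#'
#' Expects at least an `id` column; typical columns are `species`,
#' `site`, `n_obs`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_covariates_csv <- function(path) read_checked(path, "id")

#' Read a layer manifest into a network stack
#'
#' Manifest CSV `layer_name,path` with one adjacency CSV per layer
#' (paths relative to the manifest's directory unless absolute).
#'
#' @param path Manifest CSV path.
#' @return A [network_stack()].
#' @export
read_stack_manifest <- function(path) {
  man <- read_checked(path, c("layer_name", "path"))
  base <- dirname(path)
  layers <- lapply(as.character(man$path), function(p) {
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    read_adjacency_csv(full)
  })
  network_stack(layers, layer_names = as.character(man$layer_name))
}

#' Write a stack as per-layer adjacency CSVs plus a manifest
#' @param stack A [network_stack()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Manifest path, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "network") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%s.csv", prefix, stack$layer_names)
  for (k in seq_along(stack$layers))
    write_adjacency_csv(stack$layers[[k]], file.path(dir, files[k]))
  man <- data.frame(layer_name = stack$layer_names, path = files, stringsAsFactors = FALSE)
  manifest <- file.path(dir, paste0(prefix, "_manifest.csv"))
  write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}

# read.csv with existence and schema checks that name the file and the
# missing column; keeps strings as character.
read_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) stop("malformed CSV ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(path, ": missing required column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read an analysis configuration (YAML or JSON)
#'
#' Validates types and fills package defaults: `baseline` ("constant"),
#' `ilv_mode` ("none"), `constraint` ("free"), `ilv_names`,
#' `tie_window_s` (600), `use_ties` (TRUE), `level` (0.95).
#'
#' @param path YAML or JSON file.
#' @return Named list of validated settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(baseline = "constant", ilv_mode = "none", constraint = "free",
                   zero_layers = character(), ilv_names = character(),
                   tie_window_s = mnbda_defaults()$tie_window_s, use_ties = TRUE,
                   level = mnbda_defaults()$ci_level, standardize_ilvs = TRUE)
  cfg <- modifyList(defaults, as.list(cfg))
  if (!cfg$baseline %in% c("constant", "weibull"))
    stop(path, ": baseline must be 'constant' or 'weibull'", call. = FALSE)
  if (!cfg$ilv_mode %in% c("none", "additive", "multiplicative"))
    stop(path, ": invalid ilv_mode '", cfg$ilv_mode, "'", call. = FALSE)
  if (!is.numeric(cfg$tie_window_s) || cfg$tie_window_s < 0)
    stop(path, ": tie_window_s must be non-negative", call. = FALSE)
  if (!is.numeric(cfg$level) || cfg$level <= 0 || cfg$level >= 1)
    stop(path, ": level must be in (0, 1)", call. = FALSE)
  cfg
}

#' Write a reproducible run manifest
#'
#' Records the command, config and input-file MD5 hashes, the seed, the
#' package version and a timestamp -- enough to determine a rerun of any
#' deterministic command.
#'
#' @param path Output JSON path.
#' @param command Subcommand name.
#' @param inputs Character vector of input file paths to hash.
#' @param seed Integer seed used (or `NA`).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, inputs = character(), seed = NA_integer_) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(command = command,
                   inputs = as.list(setNames(unname(tools::md5sum(inputs)), inputs)),
                   seed = seed,
                   package_version = as.character(packageVersion("mnbda")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
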