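## Plain-text serialization: columnar CSV node/edge tables (a plain-CSV
## dialect of SONATA-style network files), JSON for configs, targets and
## alpha bases.  All round trips are lossless at full double precision
## (numbers serialized with 17 significant digits).

fmt_csv <- function(df, path) {
  write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
}

#' Write / read a build configuration (JSON or YAML)
#'
#' Every field of the configuration, including defaults, is written
#' explicitly, so a saved config fully determines a build.
#'
#' @param config a [build_config()].
#' @param path output path; format chosen by extension (`.json` / `.yaml`).
#' @return `read_build_config()` returns a [build_config()].
#' @export
write_build_config <- function(config, path) {
  as_plain <- function(x) {
    if (!is.list(x)) return(x)
    x <- unclass(x)
    x <- x[!vapply(x, is.null, TRUE)]  # absent on disk == NULL in memory
    lapply(x, as_plain)
  }
  obj <- as_plain(config)
  if (grepl("[.]ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else {
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' @rdname write_build_config
#' @export
read_build_config <- function(path) {
  obj <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  scalar_or_null <- function(x)
    if (is.null(x) || !length(x) || (is.atomic(x) && anyNA(x))) NULL
    else x
  cts <- lapply(obj$cell_types, function(ct)
    cell_type_spec(ct$name, ct$class, ct$layer, ct$density,
                   unlist(ct$depth_range), ct$indegree_lognormal,
                   unlist(ct$glif_pool), subclass = ct$subclass,
                   lgn_fraction = ct$lgn_fraction, lgn_rho = ct$lgn_rho) |>
      (\(x) { x$spont_rate <- scalar_or_null(ct$spont_rate); x })())
  conns <- lapply(obj$connections, function(cn)
    connection_class_spec(cn$src_type, cn$dst_type, cn$p_max, cn$sigma,
                          cn$psp_lognormal, cn$kinetics, cn$delay,
                          beta = scalar_or_null(cn$beta)))
  pool <- lapply(obj$glif_pool, function(g)
    glif_param_set(g$E_L, g$V_th, g$R_m, g$tau_m, unlist(g$asc_amps),
                   unlist(g$asc_decays), g$tau_ref))
  lgn <- obj$lgn
  lgn$field <- unlist(lgn$field)
  lgn$subtype_fractions <- unlist(lgn$subtype_fractions)
  build_config(cts, conns, pool,
               column_radius = obj$column_radius,
               core_radius = obj$core_radius,
               displacement = obj$displacement, kappa = obj$kappa,
               displacement_region_factor = obj$displacement_region_factor,
               background = obj$background, lgn = lgn)
}

#' Write / read network node and edge tables (plain-CSV dialect)
#'
#' Writes `nodes.csv` (node_id, type, x, y, z, tuning_angle,
#' indegree_target, model_id), one edge table per source population
#' (src, dst, weight, delay, family), the LGN unit table, and the build
#' config; `read_network_tables()` reconstructs the full network object
#' losslessly.
#'
#' @param network a `column_network`.
#' @param dir output directory (created).
#' @return the directory (write) or the reconstructed network (read).
#' @export
write_network_tables <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- network$neurons
  names(nodes)[names(nodes) == "id"] <- "node_id"
  fmt_csv(nodes[, c("node_id", "type", "x", "y", "z", "tuning_angle",
                    "indegree_target", "model_id")],
          file.path(dir, "nodes.csv"))
  fmt_csv(network$edges_rec, file.path(dir, "edges_recurrent.csv"))
  fmt_csv(network$edges_lgn, file.path(dir, "edges_lgn.csv"))
  fmt_csv(network$edges_bkg, file.path(dir, "edges_background.csv"))
  fmt_csv(network$lgn_units, file.path(dir, "lgn_units.csv"))
  write_build_config(network$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' @rdname write_network_tables
#' @export
read_network_tables <- function(dir) {
  config <- read_build_config(file.path(dir, "config.json"))
  nodes <- read.csv(file.path(dir, "nodes.csv"), stringsAsFactors = FALSE)
  names(nodes)[names(nodes) == "node_id"] <- "id"
  nodes$core <- sqrt(nodes$x^2 + nodes$z^2) <= config$core_radius
  rd <- function(f) {
    df <- read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    df$delay <- as.integer(df$delay)
    df$family <- as.integer(df$family)
    df
  }
  structure(list(
    neurons = nodes,
    edges_rec = rd("edges_recurrent.csv"),
    edges_lgn = rd("edges_lgn.csv"),
    edges_bkg = rd("edges_background.csv"),
    lgn_units = read.csv(file.path(dir, "lgn_units.csv"),
                         stringsAsFactors = FALSE),
    glif = glif_vectors(config$glif_pool, nodes$model_id),
    family_kinetics = build_family_kinetics(config),
    config = config
  ), class = "column_network")
}

#' Write / read spike trains as columnar CSV
#'
#' @param spikes neurons x T 0/1 matrix, or a (node_id, t_ms) data.frame.
#' @param path CSV path.
#' @param n_neurons,T_steps dimensions for matrix reconstruction.
#' @return `read_spikes_csv()` returns the (node_id, t_ms) data.frame;
#'   `spikes_matrix()` converts it back to a matrix.
#' @export
write_spikes_csv <- function(spikes, path) {
  df <- if (is.matrix(spikes)) spikes_to_df(spikes) else spikes
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_spikes_csv
#' @export
spikes_matrix <- function(df, n_neurons, T_steps) {
  m <- matrix(0L, n_neurons, T_steps)
  if (nrow(df)) m[cbind(df$node_id, df$t_ms)] <- 1L
  m
}

#' Write / read a dense voltage trace
#'
#' Dense (neuron, step) array as plain CSV, one row per neuron.
#'
#' @param v neurons x steps matrix of normalized voltages.
#' @param path CSV path.
#' @return the matrix (read) or the path (write).
#' @export
write_voltage_csv <- function(v, path) {
  write.csv(as.data.frame(v), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voltage_csv
#' @export
read_voltage_csv <- function(path) {
  unname(as.matrix(read.csv(path)))
}

#' Write / read a stimulus movie
#'
#' Dense luminance array flattened to CSV (one row per pixel, columns =
#' frames) with a JSON metadata sidecar carrying the field geometry and
#' stimulus parameters.
#'
#' @param movie a `movie` object.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return the movie (read) or the path (write).
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$frames)
  m <- matrix(movie$frames, d[1] * d[2], d[3])
  write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  meta <- movie$meta
  meta$dim <- d
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta <- jsonlite::fromJSON(readLines(paste0(path, ".json")))
  d <- as.integer(meta$dim)
  m <- as.matrix(read.csv(path))
  meta$dim <- NULL
  structure(list(frames = array(as.numeric(m), d), meta = meta),
            class = "movie")
}

#' Save / load a training checkpoint
#'
#' A checkpoint directory holds the full network tables, the optimizer
#' state (moments, step counter, magnitudes), the EMA rate statistic, and
#' the initial-weight snapshot used by the weight regularizer — everything
#' needed to resume or audit a run — as CSV/JSON.
#'
#' @param result a [train_network()] result.
#' @param dir checkpoint directory.
#' @return the directory (save) or a list mirroring the saved fields
#'   (load).
#' @export
save_checkpoint <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network_tables(result$network, file.path(dir, "network"))
  fmt_csv(data.frame(a = result$opt$a, m = result$opt$m, v = result$opt$v),
          file.path(dir, "optimizer.csv"))
  fmt_csv(data.frame(ema = result$ema), file.path(dir, "ema.csv"))
  fmt_csv(data.frame(w0_rec = result$w0_rec), file.path(dir, "w0_rec.csv"))
  writeLines(jsonlite::toJSON(list(format = 1L, u = result$opt$u),
                              auto_unbox = TRUE), file.path(dir, "meta.json"))
  if (!is.null(result$losses))
    write.csv(result$losses, file.path(dir, "losses.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::fromJSON(readLines(file.path(dir, "meta.json")))
  if (!identical(as.integer(meta$format), 1L))
    stop("load_checkpoint: unknown checkpoint format")
  opt <- read.csv(file.path(dir, "optimizer.csv"))
  list(network = read_network_tables(file.path(dir, "network")),
       opt = list(a = opt$a, m = opt$m, v = opt$v, u = as.integer(meta$u)),
       ema = read.csv(file.path(dir, "ema.csv"))$ema,
       w0_rec = read.csv(file.path(dir, "w0_rec.csv"))$w0_rec,
       losses = if (file.exists(file.path(dir, "losses.csv")))
         read.csv(file.path(dir, "losses.csv")) else NULL)
}

#' Write / read a fitted alpha basis
#'
#' @param basis an `alpha_basis` from [fit_alpha_basis()].
#' @param path JSON path.
#' @return the basis (read) or the path (write).
#' @export
write_alpha_basis <- function(basis, path) {
  obj <- list(taus = basis$taus, coeffs = unclass(basis$coeffs),
              mse = basis$mse, charge_rel_err = basis$charge_rel_err,
              horizon = basis$horizon, dt_fit = basis$dt_fit)
  writeLines(jsonlite::toJSON(obj, digits = NA), path)
  invisible(path)
}

#' @rdname write_alpha_basis
#' @export
read_alpha_basis <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  structure(list(taus = as.numeric(obj$taus), coeffs = as.matrix(obj$coeffs),
                 mse = as.numeric(obj$mse),
                 charge_rel_err = as.numeric(obj$charge_rel_err),
                 horizon = obj$horizon, dt_fit = obj$dt_fit),
            class = "alpha_basis")
}

#' Write / read a target set (JSON)
#'
#' @param targets a `target_set`.
#' @param path JSON path.
#' @return the targets (read) or the path (write).
#' @export
write_targets <- function(targets, path) {
  obj <- unclass(targets)
  obj$osi <- as.list(obj$osi)   # keep type names through JSON
  obj$dsi <- as.list(obj$dsi)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyDataFrame = TRUE)
  obj$rate_spt <- lapply(obj$rate_spt, as.numeric)
  obj$rate_evk <- lapply(obj$rate_evk, as.numeric)
  obj$osi <- unlist(obj$osi); obj$dsi <- unlist(obj$dsi)
  obj$coef <- lapply(obj$coef, function(x) x)
  structure(obj, class = "target_set")
}
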