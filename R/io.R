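#' Read and write feature matrices as delimited text with a JSON sidecar
#'
#' The matrix is stored as plain tab-separated values (one row per frame,
#' one column per feature, header = feature names) and the metadata (sampling
#' interval `dt`, feature names) in `<path>.json`. The round trip preserves
#' full double precision.
#'
#' @param X a [feature_matrix()].
#' @param path output file (e.g. `features.tsv`).
#' @return `read_feature_matrix()` returns a [feature_matrix()];
#'   `write_feature_matrix()` returns `path` invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  v <- feature_values(X)
  write_matrix(v, path)
  meta <- list(dt = attr(X, "dt"), names = colnames(X),
               n_samples = nrow(v), n_features = ncol(v))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  v <- read_matrix(path)
  feature_matrix(v, dt = meta$dt, names = meta$names)
}

#' Read/write a plain numeric matrix as tab-separated text
#'
#' Values are written with full precision (`%.17g`) so the round trip is
#' bit-exact.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix()` returns a numeric matrix (with column names when
#'   the file has a header).
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  df <- as.data.frame(formatC(m, format = "g", digits = 17))
  names(df) <- colnames(m) %||% sprintf("V%d", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  as.matrix(df)
}

#' Read coordinates from a (multi-model) PDB file
#'
#' Minimal fixed-column PDB reader for topology/reference structures and
#' short multi-model trajectories: parses ATOM records, optionally restricted
#' to one atom name (e.g. `"CA"`), and returns positions in nm (PDB files are
#' in Angstrom; conversion is explicit, never guessed). Residue numbers stay
#' 1-based as in the PDB; atom indices in all downstream APIs are 0-based.
#'
#' Binary trajectory formats (DCD/XTC) are not parsed here; convert them to
#' multi-model PDB or to a delimited feature/coordinate matrix with standard
#' MD tooling first.
#'
#' @param path PDB file.
#' @param select atom-name selection, e.g. `"CA"`; `NULL` keeps all atoms.
#' @param unit `"angstrom"` (default, converts to nm) or `"nm"` (no
#'   conversion; for synthetic files already written in nm).
#' @return List with `coords` (T x N x 3 array, nm), `atom_names`,
#'   `residue_ids` (integer), `n_models`.
#' @export
read_pdb_coords <- function(path, select = "CA", unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM records in ", path, "; malformed PDB?")
  model_brk <- cumsum(trimws(rec) == "MODEL")
  model_id <- if (max(model_brk) == 0) rep(1L, length(lines)) else
    pmax(model_brk, 1L)
  model_id <- model_id[is_atom]
  al <- lines[is_atom]
  name <- trimws(substr(al, 13, 16))
  resid <- suppressWarnings(as.integer(trimws(substr(al, 23, 26))))
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("unparseable coordinates at ATOM record ", bad, " of ", path)
  }
  keep <- if (is.null(select)) rep(TRUE, length(al)) else name == select
  if (!any(keep)) stop("selection '", select, "' matches no atoms")
  models <- unique(model_id)
  n_per <- tabulate(factor(model_id[keep], levels = models))
  if (length(unique(n_per)) != 1)
    stop("models differ in selected atom count; malformed trajectory")
  N <- n_per[1]
  Tm <- length(models)
  scale <- if (unit == "angstrom") 0.1 else 1
  coords <- array(NA_real_, c(Tm, N, 3))
  for (t in seq_len(Tm)) {
    sel <- keep & model_id == models[t]
    coords[t, , ] <- cbind(x[sel], y[sel], z[sel]) * scale
  }
  first <- keep & model_id == models[1]
  list(coords = coords, atom_names = name[first],
       residue_ids = resid[first], n_models = Tm)
}

#' Read a trajectory through the coordinate adapter
#'
#' Dispatches on file extension: `.pdb` (multi-model, via
#' [read_pdb_coords()]) or delimited text (`.tsv`/`.txt`/`.dat`) holding a
#' T x 3N flattened coordinate matrix (columns x1 y1 z1 x2 ...; already in
#' nm). DCD/XTC binaries are refused with a pointer to conversion.
#'
#' @param path trajectory file.
#' @param topology optional PDB providing atom names/residue ids for
#'   delimited inputs.
#' @param select atom-name selection applied when topology info is present.
#' @return List with `coords` (T x N x 3, nm), `atom_names`, `residue_ids`.
#' @export
read_trajectory <- function(path, topology = NULL, select = "CA") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcd", "xtc", "trr"))
    stop("binary trajectory format '.", ext, "' is not parsed natively; ",
         "convert to multi-model PDB or a delimited coordinate matrix ",
         "(e.g. with MDAnalysis/mdtraj) first")
  if (ext == "pdb") {
    p <- read_pdb_coords(path, select = select)
    return(p[c("coords", "atom_names", "residue_ids")])
  }
  m <- read_matrix(path)
  if (ncol(m) %% 3 != 0)
    stop("delimited trajectory must have 3N columns (x,y,z per atom)")
  N <- ncol(m) %/% 3
  coords <- array(NA_real_, c(nrow(m), N, 3))
  for (j in seq_len(N)) coords[, j, ] <- m[, (3 * j - 2):(3 * j)]
  atom_names <- rep(NA_character_, N)
  residue_ids <- seq_len(N)
  if (!is.null(topology)) {
    top <- read_pdb_coords(topology, select = NULL)
    keep <- if (is.null(select)) seq_along(top$atom_names) else
      which(top$atom_names == select)
    if (length(keep) != N)
      stop("topology/selection atom count (", length(keep),
           ") does not match trajectory (", N, ")")
    atom_names <- top$atom_names[keep]
    residue_ids <- top$residue_ids[keep]
  }
  list(coords = coords, atom_names = atom_names, residue_ids = residue_ids)
}

#' Write a minimal (multi-model) PDB from CA coordinates
#'
#' Synthetic-structure writer used for fixtures and round-trip tests; one CA
#' atom per residue, coordinates given in nm and written in Angstrom.
#'
#' @param coords N x 3 matrix or T x N x 3 array (nm).
#' @param path output file.
#' @param residue_ids 1-based residue numbers.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(coords, path, residue_ids = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  N <- dim(coords)[2]
  if (is.null(residue_ids)) residue_ids <- seq_len(N)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(dim(coords)[1])) {
    if (dim(coords)[1] > 1)
      writeLines(sprintf("MODEL     %4d", t), con)
    xyz <- coords[t, , , drop = TRUE] * 10 # nm -> Angstrom
    if (N == 1) xyz <- matrix(xyz, 1, 3)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(N), residue_ids, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    if (dim(coords)[1] > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Serialize / restore a fitted spectral map as structured text
#'
#' The mapping weights, normalization statistics, configuration and training
#' history are written as a single JSON document.
#'
#' @param fit a `spectral_map_fit` (or bare `target_mapping`).
#' @param path output JSON file.
#' @return `read_spectral_map()` returns a `spectral_map_fit`-like list with
#'   a `mapping` usable by [map_samples()].
#' @export
write_spectral_map <- function(fit, path) {
  if (inherits(fit, "target_mapping"))
    fit <- list(mapping = fit, history = NULL, sigma_best = NA, r = NA,
                cfg = NULL)
  m <- fit$mapping
  obj <- list(
    mapping = list(weights = m$weights, center = m$center, scale = m$scale,
                   out_shift = m$out_shift, out_scale = m$out_scale,
                   feature_names = m$feature_names),
    sigma_best = fit$sigma_best, r = fit$r,
    cfg = unclass(fit$cfg), history = fit$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_spectral_map
#' @export
read_spectral_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mp <- obj$mapping
  W <- matrix(unlist(mp$weights), nrow = length(mp$center), byrow = TRUE)
  mapping <- target_mapping(W, mp$center, mp$scale, mp$out_shift,
                            mp$out_scale, mp$feature_names)
  structure(list(mapping = mapping, history = obj$history,
                 sigma_best = obj$sigma_best, r = obj$r, cfg = obj$cfg),
            class = "spectral_map_fit")
}

#' Write a partition as a delimited label table
#'
#' One row per sample: index (0-based), state label (0 = transition state)
#' and per-state sink probabilities.
#'
#' @param part a `cv_partition` from [coarse_grain()], or a list with
#'   `labels` (and optionally `sink_probs`).
#' @param path output TSV file.
#' @export
write_partition <- function(part, path) {
  df <- data.frame(sample = seq_along(part$labels) - 1L,
                   state = part$labels)
  if (!is.null(part$sink_probs)) {
    sp <- as.data.frame(part$sink_probs)
    names(sp) <- sprintf("sink_%d", seq_len(ncol(sp)))
    df <- cbind(df, sp)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a structured run report
#'
#' Collects the headline quantities of a full run — spectral-gap history,
#' eigenspectrum, partition summary, profile tables — into one JSON report.
#'
#' @param path output JSON file.
#' @param fit optional `spectral_map_fit`.
#' @param model optional `markov_model`.
#' @param partition optional partition (list with `labels`).
#' @param profiles optional named list of profile data frames.
#' @return `path`, invisibly.
#' @export
write_report <- function(path, fit = NULL, model = NULL, partition = NULL,
                         profiles = NULL) {
  rep <- list(generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(fit))
    rep$learning <- list(sigma_best = fit$sigma_best, r = fit$r,
                         epoch_sigma = as.numeric(
                           tapply(fit$history$sigma, fit$history$epoch,
                                  mean, na.rm = TRUE)))
  if (!is.null(model))
    rep$spectrum <- list(values = model$values, sigma = model$sigma,
                         timescales = model$timescales)
  if (!is.null(partition))
    rep$partition <- list(
      k_states = length(setdiff(unique(partition$labels), 0L)),
      counts = as.list(table(partition$labels)))
  if (!is.null(profiles))
    rep$profiles <- lapply(profiles, function(p) as.data.frame(p))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
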