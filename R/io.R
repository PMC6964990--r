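#' Read and write model files
#'
#' Models are stored as flat YAML documents with sections
#' `species` (list of \{name, D, radius\}), `reactions` (list of
#' \{reactants, products, rate\}), `domain` (\{volume, levels\}),
#' `initial` (species: count) and `solver`
#' (\{C, epsilon, seed, t_final, n_samples, n_trajectories\}).
#' `readModel` validates the document and, unless `quiet = TRUE`, echoes
#' the fully resolved model — including the per-level mesoscopic rates
#' and assigned species levels — to the message stream.
#'
#' @param file path to a YAML model file.
#' @param quiet suppress the resolved-model echo.
#' @return `readModel`: an [RDModel-class]; `writeModel`: `file`,
#'   invisibly.
#' @export
readModel <- function(file, quiet = FALSE) {
  doc <- yaml::read_yaml(file)
  need <- c("species", "reactions", "domain")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("model file is missing section(s): ", paste(miss, collapse = ", "))
  sp <- lapply(doc$species, function(s) {
    if (is.null(s$name) || is.null(s$D))
      stop("each species needs at least 'name' and 'D'")
    rdSpecies(s$name, s$D, if (is.null(s$radius)) 0 else s$radius)
  })
  ch <- lapply(doc$reactions, function(r) {
    if (is.null(r$rate)) stop("each reaction needs a 'rate'")
    reaction(unlist(r$reactants), unlist(r$products), r$rate)
  })
  sv <- if (is.null(doc$solver)) list() else doc$solver
  ini <- unlist(doc$initial)
  getd <- function(x, d) if (is.null(x)) d else x
  lv <- doc$levels  # optional pinned species levels
  model <- rdModel(
    species = sp, channels = ch,
    volume = getd(doc$domain$volume, 1),
    nLevels = getd(doc$domain$levels, 7L),
    init = if (is.null(ini)) integer() else ini,
    C = getd(sv$C, 20), epsilon = getd(sv$epsilon, 0.025),
    speciesLevels = if (is.null(lv)) integer() else unlist(lv),
    tFinal = getd(sv$t_final, 1), nSamples = getd(sv$n_samples, 100L),
    nTrajectories = getd(sv$n_trajectories, 1L),
    seed = getd(sv$seed, NA_integer_),
    name = getd(doc$name, sub("\\.[^.]*$", "", basename(file))))
  validObject(model)
  if (!quiet) {
    message("resolved model '", model@name, "':")
    for (ln in utils::capture.output(show(model))) message("  ", ln)
    lvls <- .resolveLevels(model)
    message("  assigned finest levels: ",
            paste(names(lvls), lvls, sep = "=", collapse = ", "))
    tab <- mesoRateTable(model)
    if (nrow(tab))
      for (ln in utils::capture.output(print(tab, row.names = FALSE)))
        message("  ", ln)
  }
  model
}

#' @rdname readModel
#' @param model an [RDModel-class].
#' @export
writeModel <- function(model, file) {
  stopifnot(is(model, "RDModel"))
  st <- speciesTable(model)
  lv <- model@speciesLevels[!is.na(model@speciesLevels)]
  doc <- list(
    name = model@name,
    species = lapply(seq_len(nrow(st)), function(i)
      list(name = st$name[i], D = st$D[i], radius = st$radius[i])),
    reactions = lapply(model@channels, function(ch)
      list(reactants = as.list(ch@reactants),
           products = as.list(ch@products), rate = ch@rate)),
    domain = list(volume = model@volume, levels = model@nLevels),
    initial = as.list(model@init),
    solver = list(C = model@transferC, epsilon = model@epsilon,
                  t_final = model@tFinal, n_samples = model@nSamples,
                  n_trajectories = model@nTrajectories))
  if (!is.na(model@seed)) doc$solver$seed <- model@seed
  if (length(lv)) doc$levels <- as.list(lv)
  yaml::write_yaml(doc, file, precision = 15)
  invisible(file)
}

## header line carrying provenance for all delimited writers
.headerLine <- function(model = NULL, seed = NA) {
  paste0("# hrdme",
         if (!is.null(model)) paste0(" model=", model@name),
         if (!is.na(seed)) paste0(" seed=", seed),
         " written=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Write trajectories and summaries as delimited tables
#'
#' `writeTrajectory` writes one trajectory in wide format (a `time`
#' column plus one column per species); `writeEnsembleSeries` writes the
#' ensemble means and standard deviations (`mean.X` / `sd.X` columns);
#' `writeRebinds` writes one rebinding duration per line. All writers
#' start with a `#` comment header carrying the model name and seed.
#'
#' @param x the object to write.
#' @param file output path.
#' @param model optional [RDModel-class] for the header.
#' @param seed optional seed for the header.
#' @return `file`, invisibly.
#' @export
writeTrajectory <- function(x, file, model = NULL, seed = NA) {
  stopifnot(is(x, "Trajectory"))
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(.headerLine(model, seed), con)
  write.table(data.frame(time = x@times, x@counts, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrajectory
#' @export
writeEnsembleSeries <- function(x, file, model = NULL, seed = NA) {
  if (is(x, "TrajectoryEnsemble")) x <- ensembleSeries(x)
  stopifnot(is(x, "EnsembleSeries"))
  mu <- x@mean; colnames(mu) <- paste0("mean.", colnames(mu))
  sdm <- x@sd; colnames(sdm) <- paste0("sd.", colnames(sdm))
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(.headerLine(model, seed), con)
  write.table(data.frame(time = x@times, mu, sdm, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrajectory
#' @export
writeRebinds <- function(x, file, model = NULL, seed = NA) {
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(.headerLine(model, seed), con)
  writeLines("rebindTime", con)
  writeLines(format(x, scientific = TRUE, digits = 10, trim = TRUE), con)
  invisible(file)
}
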