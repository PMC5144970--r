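#' Published environmental setting grids
#'
#' The six settings used for each of the four environmental parameters in the
#' reaction-norm experiment: temperature (degrees C), added NaCl (M), added
#' sucrose (% w/v) and medium pH.
#'
#' @return Named list of numeric vectors, one per environmental parameter.
#' @export
#' @examples
#' default_env_params()$temperature
default_env_params <- function() {
  list(
    temperature = c(15, 20, 25, 30, 35, 40),
    salt        = c(0, 0.2, 0.4, 0.8, 1.2, 1.6),
    sucrose     = c(0.015, 0.15, 1.5, 5, 15, 30),
    pH          = c(4.0, 5.0, 5.8, 7.0, 8.0, 9.0)
  )
}

#' Default genotype panel
#'
#' The 26-strain panel used in the reaction-norm experiment: the wild-type
#' control 4200 plus 25 knockout strains, each assigned to the epigenetic
#' mechanism its deleted gene belongs to.
#'
#' @return A data.frame with columns `genotype` and `mechanism`.
#' @export
default_genotypes <- function() {
  g <- c(
    "4200"  = "control",
    "dim-2" = "DNA methylation", "dmm-1" = "DNA methylation",
    "dmm-2" = "DNA methylation",
    "dim-5" = "histone methylation", "set-1" = "histone methylation",
    "set-2" = "histone methylation", "set-7" = "histone methylation",
    "npf"   = "histone methylation",
    "nst-1" = "histone deacetylation", "nst-2" = "histone deacetylation",
    "nst-4" = "histone deacetylation", "nst-6" = "histone deacetylation",
    "nst-7" = "histone deacetylation", "hda-1" = "histone deacetylation",
    "hda-2" = "histone deacetylation", "hda-4" = "histone deacetylation",
    "qde-1" = "RNA interference", "qde-2" = "RNA interference",
    "dcl-1" = "RNA interference", "dcl-2" = "RNA interference",
    "qip"   = "RNA interference",
    "aof2"  = "other", "elp3" = "other", "lid2" = "other", "ngf-1" = "other"
  )
  data.frame(genotype = names(g), mechanism = unname(g),
             stringsAsFactors = FALSE)
}

#' Enumerate a full factorial assay design
#'
#' Expands every combination of genotype, environmental parameter, parameter
#' setting and replicate into one row per race-tube assay, in deterministic
#' (genotype, parameter, setting, replicate) order.
#'
#' @param genotypes data.frame with columns `genotype` and `mechanism`
#'   (one row per strain), as returned by [default_genotypes()].
#' @param env_params named list mapping each environmental parameter to its
#'   numeric settings vector, as returned by [default_env_params()].
#' @param n_replicates number of replicate assays per cell (>= 1).
#' @return A data.frame (class `design_table`) with columns `genotype`,
#'   `mechanism`, `env_param`, `setting`, `replicate`.
#' @export
#' @examples
#' d <- enumerate_design(default_genotypes(), default_env_params(), 5)
#' nrow(d)  # 3120
enumerate_design <- function(genotypes = default_genotypes(),
                             env_params = default_env_params(),
                             n_replicates = 5) {
  stopifnot(is.data.frame(genotypes),
            all(c("genotype", "mechanism") %in% names(genotypes)))
  if (anyDuplicated(genotypes$genotype))
    stop("duplicate genotype labels in design: ",
         paste(unique(genotypes$genotype[duplicated(genotypes$genotype)]),
               collapse = ", "))
  if (!is.list(env_params) || length(env_params) == 0L ||
      is.null(names(env_params)) || any(!nzchar(names(env_params))))
    stop("env_params must be a non-empty named list of settings vectors")
  if (any(vapply(env_params, length, 1L) == 0L))
    stop("each environmental parameter needs at least one setting")
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      n_replicates < 1 || n_replicates != round(n_replicates))
    stop("n_replicates must be a single integer >= 1")

  per_param <- lapply(names(env_params), function(p) {
    data.frame(env_param = p, setting = sort(env_params[[p]]),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, per_param)

  out <- merge(genotypes, cells, by = NULL)        # cartesian product
  out <- out[rep(seq_len(nrow(out)), each = n_replicates), , drop = FALSE]
  out$replicate <- rep(seq_len(n_replicates), length.out = nrow(out))
  out <- out[order(out$genotype,
                   match(out$env_param, names(env_params)),
                   out$setting, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("design_table", "data.frame")
  out
}

#' Expected shared genetic background after backcrossing
#'
#' The donor genome fraction halves at the initial cross and again at each
#' backcross, so after `n` backcrosses the recurrent parent contributes
#' \eqn{100 (1 - 2^{-(n+1)})} percent of the genome. Five backcrosses give
#' the familiar 98.44%.
#'
#' @param n_backcrosses non-negative integer count of backcross generations
#'   (0 = a single cross).
#' @return Percent of shared genetic background (numeric).
#' @export
#' @examples
#' expected_shared_background(5)  # 98.4375
expected_shared_background <- function(n_backcrosses) {
  if (!is.numeric(n_backcrosses) || any(n_backcrosses < 0) ||
      any(n_backcrosses != round(n_backcrosses)))
    stop("n_backcrosses must be a non-negative integer")
  100 * (1 - 0.5^(n_backcrosses + 1))
}
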