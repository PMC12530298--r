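#' Names of the bundled empirical substitution models
#'
#' The package ships PAML-format matrix files for five widely used empirical
#' amino acid replacement models: Blosum62, Dayhoff, JTT, LG and WAG. Any
#' other model (cpREV, DCMut, FLU, HIVb/HIVw, mtART, mtMAM, mtREV, mtZOA,
#' rtREV, VT, ...) can be supplied as a user PAML-format `.dat` file via
#' [load_model()].
#'
#' @return Character vector of registry names accepted by [load_model()].
#' @export
#' @examples
#' aa_models()
aa_models <- function() {
  sort(c("Blosum62", "Dayhoff", "JTT", "LG", "WAG"))
}

#' Load an empirical amino acid substitution model
#'
#' Reads an empirical replacement model — either one of the bundled models
#' (see [aa_models()]) or a PAML-format matrix file — and compiles it into a
#' normalized reversible rate matrix with a cached spectral decomposition.
#'
#' A PAML-format file contains the lower triangle of the symmetric 20x20
#' exchangeability matrix `S` (rows 2..20, residue order
#' `ARNDCQEGHILKMFPSTWYV`) followed by the 20 stationary frequencies `pi`.
#' The rate matrix is built as `Q[i,j] = S[i,j] * pi[j]` for `i != j`, the
#' diagonal is set so rows sum to zero, and `Q` is rescaled so that the
#' expected substitution rate at stationarity, `-sum(pi * diag(Q))`, equals
#' one. Distances estimated under the model are therefore in units of
#' expected substitutions per site.
#'
#' @param source A registry name among [aa_models()] or the path to a
#'   PAML-format matrix file.
#' @param name Optional model name; defaults to the registry name or the
#'   file name without extension.
#' @return An object of class `aa_model`: a list with elements `name`, `S`
#'   (exchangeabilities), `pi` (stationary frequencies), `Q` (normalized
#'   rate matrix) and `spectrum` (eigendecomposition of the symmetrized rate
#'   matrix, cached for fast matrix exponentials).
#' @seealso [transition_probabilities()], [uniform_aa_model()]
#' @export
#' @examples
#' lg <- load_model("LG")
#' lg
#' # unit expected rate by construction:
#' -sum(lg$pi * diag(lg$Q))
load_model <- function(source, name = NULL) {
  stopifnot(is.character(source), length(source) == 1)
  if (source %in% aa_models()) {
    path <- system.file("extdata", "models", paste0(source, ".dat"),
                        package = "aasd", mustWork = TRUE)
    if (is.null(name)) name <- source
  } else if (file.exists(source)) {
    path <- source
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(source))
  } else {
    stop("unknown model '", source, "': not a bundled model (",
         paste(aa_models(), collapse = ", "), ") and not an existing file")
  }
  parsed <- read_paml_matrix(path)
  compile_model(name, parsed$S, parsed$pi)
}

# Parse a PAML-style amino acid matrix file: 190 lower-triangle
# exchangeabilities (row-wise) followed by 20 stationary frequencies.
read_paml_matrix <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tokens <- unlist(strsplit(paste(txt, collapse = " "), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  if (anyNA(vals)) {
    stop("malformed matrix file '", path, "': non-numeric token '",
         tokens[which(is.na(vals))[1]], "'")
  }
  if (length(vals) < 210) {
    stop("malformed matrix file '", path, "': expected at least 210 numbers ",
         "(190 exchangeabilities + 20 frequencies), found ", length(vals))
  }
  tri <- vals[1:190]
  pi <- vals[191:210]
  S <- matrix(0, 20, 20, dimnames = list(AA_RESIDUES, AA_RESIDUES))
  k <- 1L
  for (i in 2:20) {
    S[i, 1:(i - 1)] <- tri[k:(k + i - 2L)]
    k <- k + i - 1L
  }
  S <- S + t(S)
  neg <- which(S < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative exchangeability S[", AA_RESIDUES[neg[1, 1]], ",",
         AA_RESIDUES[neg[1, 2]], "] = ", S[neg[1, 1], neg[1, 2]],
         " in '", path, "'")
  }
  if (abs(sum(pi) - 1) > 1e-3) {
    stop("stationary frequencies in '", path, "' sum to ",
         format(sum(pi)), ", not 1")
  }
  if (any(pi <= 0)) {
    stop("non-positive stationary frequency pi[",
         AA_RESIDUES[which(pi <= 0)[1]], "] in '", path, "'")
  }
  names(pi) <- AA_RESIDUES
  list(S = S, pi = pi / sum(pi))
}

# Build the normalized reversible rate matrix and cache its spectrum.
# The symmetrized matrix diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric for
# reversible Q, so its eigendecomposition is real and numerically stable;
# P(t) = E1 diag(exp(lambda t)) E2 with E1, E2 the back-transformed
# eigenvector matrices.
compile_model <- function(name, S, pi) {
  stopifnot(isTRUE(all.equal(S, t(S), tolerance = 1e-12)))
  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate model '", name, "': zero expected rate")
  Q <- Q / mu
  sp <- sqrt(pi)
  A <- Q * (sp %o% (1 / sp))
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  spectrum <- list(
    lambda = eig$values,
    E1 = eig$vectors / sp,           # diag(1/sqrt(pi)) %*% V
    E2 = t(eig$vectors * sp)         # t(V) %*% diag(sqrt(pi))
  )
  structure(
    list(name = name, S = S, pi = pi, Q = Q, spectrum = spectrum),
    class = "aa_model"
  )
}

#' Equal-rates amino acid model
#'
#' The 20-state analogue of the Jukes--Cantor model: all exchangeabilities
#' equal and uniform stationary frequencies. Under this model the transition
#' probability has the closed form
#' `P[i,j](t) = (1 - exp(-20/19 * t)) / 20` for `i != j`, and the maximum
#' likelihood distance between two sequences with observed mismatch
#' proportion `p` is `-(19/20) * log(1 - (20/19) * p)`. These closed forms
#' make the model the natural analytic reference point for the numerical
#' machinery.
#'
#' @return An `aa_model` object named `"EqualRates"`.
#' @export
#' @examples
#' m <- uniform_aa_model()
#' transition_probabilities(m, 0.3)[1, 2]
#' (1 - exp(-20 / 19 * 0.3)) / 20
uniform_aa_model <- function() {
  S <- matrix(1, 20, 20, dimnames = list(AA_RESIDUES, AA_RESIDUES))
  diag(S) <- 0
  pi <- stats::setNames(rep(1 / 20, 20), AA_RESIDUES)
  compile_model("EqualRates", S, pi)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Evaluates the matrix exponential of the model's rate matrix at branch
#' length `t` via the cached spectral decomposition. Rows sum to one;
#' negative entries from floating-point round-off (magnitude below 1e-12)
#' are clipped to zero.
#'
#' @param model An `aa_model` object.
#' @param t Branch length in expected substitutions per site (finite,
#'   non-negative).
#' @return A 20x20 row-stochastic matrix with residue dimnames.
#' @export
#' @examples
#' wag <- load_model("WAG")
#' P <- transition_probabilities(wag, 0.1)
#' range(rowSums(P))
transition_probabilities <- function(model, t) {
  stopifnot(inherits(model, "aa_model"))
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("branch length 't' must be a single finite non-negative number")
  }
  sp <- model$spectrum
  P <- sp$E1 %*% (exp(sp$lambda * t) * sp$E2)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_RESIDUES, AA_RESIDUES)
  P
}

#' @export
print.aa_model <- function(x, ...) {
  cat("<aa_model> ", x$name, "\n", sep = "")
  cat("  20-state reversible empirical model, unit expected rate\n")
  cat("  stationary frequencies: ",
      paste0(AA_RESIDUES[1:5], "=", signif(x$pi[1:5], 3), collapse = " "),
      " ...\n", sep = "")
  invisible(x)
}
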