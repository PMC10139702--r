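#' Read an empirical amino acid model file (PAML .dat layout)
#'
#' Parses the classic plain-text layout used for empirical amino acid
#' replacement matrices: 19 rows giving the lower triangle of the symmetric
#' 20x20 exchangeability matrix (residue order `ARNDCQEGHILKMFPSTWYV`),
#' followed by 20 equilibrium frequencies. Tokens may be split across lines
#' arbitrarily; trailing free-text comments are ignored.
#'
#' @param path Path to a model file.
#' @return A list with components `exchangeabilities` (symmetric 20x20
#'   matrix, zero diagonal) and `frequencies` (named length-20 vector).
#' @export
read_paml_dat <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "")
  num <- suppressWarnings(as.numeric(toks))
  num <- num[!is.na(num)]
  if (length(num) < 210) {
    stop("model file ", path, ": expected at least 210 numeric values ",
         "(190 exchangeabilities + 20 frequencies), found ", length(num),
         call. = FALSE)
  }
  s <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  k <- 1L
  for (i in 2:20) {
    s[i, 1:(i - 1)] <- num[k:(k + i - 2L)]
    k <- k + i - 1L
  }
  s <- s + t(s)
  freq <- num[191:210]
  names(freq) <- AA_CODES
  list(exchangeabilities = s, frequencies = freq)
}

#' Build a normalized reversible rate matrix
#'
#' Constructs a 20-state general time-reversible rate matrix from symmetric
#' exchangeabilities `s` and equilibrium frequencies `pi`:
#' `Q[i,j] = s[i,j] * pi[j]` for `i != j`, diagonal chosen so rows sum to
#' zero, and the whole matrix rescaled so that the expected number of
#' substitutions per unit time at stationarity, `-sum(pi * diag(Q))`,
#' equals 1. Branch lengths are then expected substitutions per site.
#'
#' @param exchangeabilities Symmetric nonnegative 20x20 matrix, zero
#'   diagonal.
#' @param frequencies Strictly positive length-20 vector summing to 1
#'   (within 1e-6; renormalized exactly).
#' @param name Model label stored on the result.
#' @return An object of class `aa_model`: a list with fields `name`,
#'   `exchangeabilities`, `frequencies`, `rate_matrix`, and a cached
#'   spectral decomposition used by [transition_matrix()].
#' @export
build_rate_matrix <- function(exchangeabilities, frequencies,
                              name = "custom") {
  s <- as.matrix(exchangeabilities)
  if (!identical(dim(s), c(20L, 20L)))
    stop("exchangeabilities must be a 20x20 matrix", call. = FALSE)
  if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s))))
    stop("exchangeabilities must be symmetric", call. = FALSE)
  if (any(s < 0))
    stop("exchangeabilities must be nonnegative", call. = FALSE)
  if (all(s[row(s) != col(s)] == 0))
    stop("all exchangeabilities are zero: no substitution process",
         call. = FALSE)
  pi <- as.numeric(frequencies)
  if (length(pi) != 20L)
    stop("frequencies must have length 20", call. = FALSE)
  if (any(pi <= 0))
    stop("all frequencies must be strictly positive", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(pi)), ")",
         call. = FALSE)
  pi <- pi / sum(pi)
  names(pi) <- AA_CODES
  diag(s) <- 0

  q <- s * rep(pi, each = 20)        # Q[i,j] = s[i,j] * pi[j]
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))           # substitutions per unit time
  q <- q / mu
  dimnames(q) <- list(AA_CODES, AA_CODES)

  # Symmetric similarity transform diag(sqrt(pi)) Q diag(1/sqrt(pi)) has the
  # same eigenvalues as Q and a numerically stable symmetric eigenproblem.
  sq <- sqrt(pi)
  b <- q * (sq %o% (1 / sq))
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  decomp <- list(
    values = eig$values,
    left  = eig$vectors / sq,        # diag(1/sqrt(pi)) %*% V
    right = t(eig$vectors * sq)      # t(V) %*% diag(sqrt(pi))
  )

  structure(
    list(name = name, exchangeabilities = s, frequencies = pi,
         rate_matrix = q, decomp = decomp),
    class = "aa_model")
}

#' Construct an amino acid substitution model
#'
#' Loads one of the empirical amino acid replacement models shipped with the
#' package (JTT, WAG, LG) or the 20-state equal-rates model, optionally
#' replacing the model's equilibrium frequencies with frequencies observed
#' in an alignment (the "+F" option).
#'
#' @param name One of `"JTT"`, `"WAG"`, `"LG"`, `"EQ"` (case-insensitive),
#'   or a path to a model file in the layout read by [read_paml_dat()].
#' @param frequencies Optional length-20 replacement frequency vector, or a
#'   protein alignment (character matrix, see [read_alignment()]) whose
#'   observed residue frequencies are used (+F).
#' @return An `aa_model` object (see [build_rate_matrix()]).
#' @examples
#' m <- aa_model("JTT")
#' p <- transition_matrix(m, 0.1)
#' range(rowSums(p))  # rows of P(t) sum to 1
#' @export
aa_model <- function(name = c("JTT", "WAG", "LG", "EQ"), frequencies = NULL) {
  if (length(name) > 1L) name <- name[1L]
  key <- toupper(name)
  if (key %in% c("JTT", "WAG", "LG")) {
    path <- system.file("extdata", "models",
                        paste0(tolower(key), ".dat"), package = "aaconv",
                        mustWork = TRUE)
    dat <- read_paml_dat(path)
  } else if (key %in% c("EQ", "EQUAL", "POISSON")) {
    s <- matrix(1, 20, 20); diag(s) <- 0
    dat <- list(exchangeabilities = s,
                frequencies = rep(1 / 20, 20))
    key <- "EQ"
  } else if (file.exists(name)) {
    dat <- read_paml_dat(name)
    key <- basename(name)
  } else {
    stop("unknown model '", name,
         "': use JTT, WAG, LG, EQ, or a model file path", call. = FALSE)
  }
  if (!is.null(frequencies)) {
    if (is.matrix(frequencies) && is.character(frequencies)) {
      frequencies <- observed_frequencies(frequencies)
      key <- paste0(key, "+F")
    } else if (length(frequencies) == 20L) {
      key <- paste0(key, "+F")
    } else {
      stop("frequencies must be a length-20 vector or a protein alignment",
           call. = FALSE)
    }
    dat$frequencies <- frequencies
  }
  build_rate_matrix(dat$exchangeabilities, dat$frequencies, name = key)
}

#' Observed residue frequencies of an alignment
#'
#' Counts residues across the whole alignment, ignoring gaps and ambiguity
#' symbols, with one pseudo-count per residue so that every frequency is
#' strictly positive (a requirement of reversible models).
#'
#' @param alignment Character matrix of aligned residues.
#' @return Named length-20 frequency vector summing to 1.
#' @export
observed_frequencies <- function(alignment) {
  idx <- aa_index(as.vector(alignment))
  counts <- tabulate(idx[idx > 0L], nbins = 20L) + 1
  setNames(counts / sum(counts), AA_CODES)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computes transition probabilities from the model's cached spectral
#' decomposition. Rows are renormalized only when the deviation from 1 is
#' within `1e-8`; larger deviations indicate a malformed model and raise an
#' error rather than being masked.
#'
#' @param model An `aa_model`.
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return Row-stochastic 20x20 matrix of substitution probabilities.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "aa_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a single nonnegative number", call. = FALSE)
  if (t == 0) {
    p <- diag(20)
    dimnames(p) <- list(AA_CODES, AA_CODES)
    return(p)
  }
  d <- model$decomp
  p <- d$left %*% (exp(d$values * t) * d$right)
  rs <- rowSums(p)
  if (max(abs(rs - 1)) > 1e-8)
    stop("transition matrix rows deviate from 1 by ",
         format(max(abs(rs - 1))), "; model is malformed", call. = FALSE)
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- list(AA_CODES, AA_CODES)
  p
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Amino acid substitution model:", x$name, "\n")
  cat("  normalized reversible rate matrix (20 states, PAML residue order)\n")
  cat("  frequency range: [", format(min(x$frequencies), digits = 4), ", ",
      format(max(x$frequencies), digits = 4), "]\n", sep = "")
  invisible(x)
}
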