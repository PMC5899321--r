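# Amino-acid alphabet and empirical substitution matrices.
# State order follows the PAML .dat convention throughout the package.

#' Amino-acid state order used by chronoforge
#'
#' One-letter codes in the fixed order shared by the packaged empirical
#' matrices (PAML convention): ARNDCQEGHILKMFPSTWYV.
#'
#' @return Character vector of length 20.
#' @export
aa_states <- function() {
  strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
}

# Characters normalized to "unknown" on input: ambiguity codes, rare
# residues, gaps handled separately.
.aa_unknown_chars <- c("X", "?", "B", "Z", "J", "U", "O", "*", ".")

#' Read an empirical amino-acid model in PAML text format
#'
#' Parses a lower-triangular exchangeability table followed by the 20
#' equilibrium frequencies, the layout used by published LG/WAG tables.
#'
#' @param path Path to the `.dat` file.
#' @return List with `rho` (symmetric 20x20 exchangeability matrix, zero
#'   diagonal) and `freqs` (length-20 frequency vector summing to 1).
#' @export
read_paml_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 20L) {
    stop("expected 19 matrix rows plus one frequency row in ", path)
  }
  rho <- matrix(0, 20, 20, dimnames = list(aa_states(), aa_states()))
  for (i in 2:20) {
    vals <- as.numeric(strsplit(trimws(lines[i - 1L]), "\\s+")[[1]])
    if (length(vals) != i - 1L) stop("malformed row ", i, " in ", path)
    rho[i, seq_len(i - 1L)] <- vals
  }
  rho <- rho + t(rho)
  freqs <- as.numeric(strsplit(trimws(lines[20L]), "\\s+")[[1]])
  if (length(freqs) != 20L) stop("malformed frequency row in ", path)
  freqs <- freqs / sum(freqs)
  names(freqs) <- aa_states()
  list(rho = rho, freqs = freqs)
}

# Cached accessor for the packaged empirical matrices.
.empirical_model <- function(name) {
  key <- paste0("aamodel_", name)
  if (!is.null(.cf_env[[key]])) return(.cf_env[[key]])
  path <- system.file("extdata", paste0(name, ".dat"), package = "chronoforge")
  if (!nzchar(path)) stop("no packaged matrix named '", name, "'")
  .cf_env[[key]] <- read_paml_matrix(path)
  .cf_env[[key]]
}

#' Uniform (Poisson) exchangeabilities
#' @return 20x20 matrix of ones with zero diagonal.
#' @export
uniform_exchangeabilities <- function() {
  rho <- matrix(1, 20, 20, dimnames = list(aa_states(), aa_states()))
  diag(rho) <- 0
  rho
}
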