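#' Residual current fraction under simple pore block
#'
#' The conductance multiplier applied to a channel's maximal conductance
#' when a drug at concentration `concentration` blocks it with the given
#' IC50 and Hill coefficient:
#' `1 / (1 + (concentration / ic50)^hill)`.
#'
#' @param concentration Drug concentration, uM (>= 0).
#' @param ic50 Half-maximal inhibitory concentration, uM (> 0).
#' @param hill Hill coefficient (> 0, default 1).
#' @return Residual fraction in `[0, 1]`.
#' @export
residual_fraction <- function(concentration, ic50, hill = 1) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(hill <= 0)) stop("hill must be > 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  1 / (1 + (concentration / ic50)^hill)
}

#' Drug specification
#'
#' @param name Drug name.
#' @param ic50 Named numeric vector of IC50s (uM) for a subset of
#'   `INa`, `ICaL`, `Ito`, `IKr`.  Channels absent from the vector are not
#'   affected by the drug (residual 1), reflecting "no effect or IC50 much
#'   higher than tested concentrations".
#' @param concentrations Tested concentrations, uM, strictly ascending.
#' @param frequencies Pacing frequencies (Hz) used for this drug; the slow
#'   rate is 0.2 or 0.25 Hz depending on the compound.
#' @param tdp_class CredibleMeds torsade class: `"1"` (known risk),
#'   `"2"` (conditional risk) or `"NC"` (not classified).
#' @param hill Hill coefficient applied to all channels (default 1).
#' @param n_fibers Number of rabbit preparations tested (metadata).
#' @param eftpc_max Maximum effective free therapeutic plasma
#'   concentration, uM (optional metadata; unused by computations).
#' @return An object of class `drug_spec`.
#' @export
drug_spec <- function(name, ic50, concentrations, frequencies,
                      tdp_class, hill = 1, n_fibers = NA_integer_,
                      eftpc_max = NA_real_) {
  targetable <- c("INa", "ICaL", "Ito", "IKr")
  if (length(ic50)) {
    bad <- setdiff(names(ic50), targetable)
    if (length(bad)) stop("unknown channel key(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(ic50)) || any(ic50 <= 0)) stop("IC50s must be finite and > 0")
  }
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly ascending")
  }
  if (!tdp_class %in% c("1", "2", "NC")) {
    stop("tdp_class must be one of \"1\", \"2\", \"NC\"")
  }
  slow <- frequencies[frequencies < 1]
  structure(
    list(name = name, ic50 = ic50, hill = hill,
         concentrations = as.numeric(concentrations),
         frequencies = as.numeric(frequencies),
         slow_rate = if (length(slow)) min(slow) else NA_real_,
         tdp_class = tdp_class, n_fibers = n_fibers,
         eftpc_max = eftpc_max),
    class = "drug_spec"
  )
}

#' @export
print.drug_spec <- function(x, ...) {
  cat("<drug_spec>", x$name, " TdP class:", x$tdp_class, "\n")
  if (length(x$ic50)) {
    cat("  IC50 (uM):", paste(names(x$ic50), signif(x$ic50, 3), collapse = "  "), "\n")
  }
  cat("  concentrations (uM):", paste(x$concentrations, collapse = ", "), "\n")
  cat("  frequencies (Hz):", paste(x$frequencies, collapse = ", "), "\n")
  invisible(x)
}

#' Per-current block residuals for a dose of a drug
#'
#' Applies [residual_fraction()] to each channel the drug targets; all
#' other currents keep residual 1.  Concentrations outside the drug's
#' tested list are allowed (in-silico extrapolation beyond solubility
#' limits) but flagged in the `"extrapolated"` attribute.
#'
#' @param drug A [drug_spec()].
#' @param concentration Dose in uM (>= 0).
#' @return A [block_set_values()] vector with attribute `"extrapolated"`.
#' @export
block_set <- function(drug, concentration) {
  stopifnot(inherits(drug, "drug_spec"), concentration >= 0)
  res <- setNames(rep(1, 12L), current_ids())
  for (ch in names(drug$ic50)) {
    res[ch] <- residual_fraction(concentration, drug$ic50[[ch]], drug$hill)
  }
  out <- block_set_values(res)
  attr(out, "extrapolated") <-
    concentration > 0 && !concentration %in% drug$concentrations
  out
}

#' Load a drug library from CSV
#'
#' Reads a drug library with one row per compound and columns `name`,
#' `ic50_INa`, `ic50_ICaL`, `ic50_Ito`, `ic50_IKr` (uM; empty = channel not
#' affected), `hill`, `concentrations` (semicolon-separated uM),
#' `frequencies` (semicolon-separated Hz), `n_fibers` and `tdp_class`.
#' The bundled library (`default_drug_library_path()`) contains the 14
#' reference compounds with their experimental IC50s, tested concentrations,
#' pacing rates and CredibleMeds classes.
#'
#' @param path CSV path; defaults to the bundled library.
#' @return Named list of [drug_spec()] objects.
#' @export
load_drug_library <- function(path = default_drug_library_path()) {
  if (!file.exists(path)) stop("drug library file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "ic50_INa", "ic50_ICaL", "ic50_Ito", "ic50_IKr",
            "hill", "concentrations", "frequencies", "n_fibers", "tdp_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug library missing column(s): ", paste(miss, collapse = ", "))
  parse_nums <- function(s) as.numeric(strsplit(s, ";")[[1]])
  drugs <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    ic50 <- c(INa = row$ic50_INa, ICaL = row$ic50_ICaL,
              Ito = row$ic50_Ito, IKr = row$ic50_IKr)
    ic50 <- ic50[!is.na(ic50)]
    if (any(ic50 <= 0)) {
      stop("drug ", row$name, ": IC50 values must be positive")
    }
    drug_spec(
      name = row$name, ic50 = ic50,
      concentrations = parse_nums(row$concentrations),
      frequencies = parse_nums(row$frequencies),
      tdp_class = as.character(row$tdp_class),
      hill = row$hill, n_fibers = row$n_fibers,
      eftpc_max = if ("eftpc_max" %in% names(df)) row$eftpc_max else NA_real_
    )
  })
  setNames(drugs, df$name)
}

#' @rdname load_drug_library
#' @export
default_drug_library_path <- function() {
  system.file("extdata", "drug_library.csv", package = "purkinjetrials",
              mustWork = TRUE)
}
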