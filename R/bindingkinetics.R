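# Competitive-inhibition kinetics, surface plasmon resonance steady-state
# affinity, and conversion of equilibrium constants to binding free
# energies (delta G = -RT ln K).

GAS_CONSTANT <- 8.314  # J mol^-1 K^-1

#' Competitive-inhibition rate law
#'
#' `v = Vmax S / (KM (1 + I/Ki) + S)`: the inhibitor raises the apparent
#' Michaelis constant and leaves Vmax untouched. Strictly decreasing in `I`;
#' tends to `Vmax` as `S` grows.
#'
#' @param S substrate concentration (mM), > 0.
#' @param I inhibitor concentration (mM), >= 0.
#' @param Vmax,KM,Ki kinetic parameters, all > 0 (`KM`, `Ki` in mM; `Vmax`
#'   in whatever rate unit the data use -- the model is unit-agnostic in
#'   `Vmax`).
#' @return rate `v`, same unit as `Vmax`.
#' @export
competitive_rate <- function(S, I, Vmax, KM, Ki) {
  if (any(Vmax <= 0) || any(KM <= 0) || any(Ki <= 0))
    stop("kinetic parameters must be positive")
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  if (any(I < 0)) stop("inhibitor concentrations must be non-negative")
  Vmax * S / (KM * (1 + I / Ki) + S)
}

#' Fit the competitive-inhibition model and Dixon diagnostic
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the competitive model to
#' `(S, I, v)` rate data, with uniform weights. The Dixon diagnostic fits a
#' straight line `1/v` against `I` per substrate level; for competitive
#' inhibition all lines intersect at `I = -Ki`, so the mean pairwise
#' intersection abscissa is reported alongside the regression estimate.
#'
#' @param data data.frame with columns `S` (mM), `I` (mM), `v` (rate).
#' @param start optional named list `Vmax`, `KM`, `Ki` of starting values.
#' @return list: `params` (Vmax, KM, Ki), `se` (standard errors),
#'   `dixon_ki` (the Dixon-intersection estimate of Ki),
#'   `fit` (the underlying `nls` object).
#' @export
fit_competitive_ki <- function(data, start = NULL) {
  stopifnot(all(c("S", "I", "v") %in% names(data)))
  if (length(unique(data$S)) < 2 || length(unique(data$I)) < 3)
    stop("non-identifiable design: need >= 2 substrate and >= 3 inhibitor levels")
  if (is.null(start)) {
    start <- list(Vmax = max(data$v) * 1.5,
                  KM = stats::median(data$S),
                  Ki = stats::median(data$I[data$I > 0]))
  }
  fit <- minpack.lm::nlsLM(
    v ~ Vmax * S / (KM * (1 + I / Ki) + S),
    data = data, start = start,
    lower = c(Vmax = 1e-12, KM = 1e-12, Ki = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  params <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  # Dixon: 1/v vs I lines per substrate level, pairwise intersections
  lines <- lapply(split(data, data$S), function(d) {
    stats::coef(stats::lm(I(1 / v) ~ I, data = d))
  })
  inter <- c()
  nl <- length(lines)
  for (i in seq_len(nl - 1)) for (j in (i + 1):nl) {
    a1 <- lines[[i]][1]; b1 <- lines[[i]][2]
    a2 <- lines[[j]][1]; b2 <- lines[[j]][2]
    if (abs(b1 - b2) > 1e-12) inter <- c(inter, (a2 - a1) / (b1 - b2))
  }
  list(params = params, se = se,
       dixon_ki = -mean(inter), fit = fit)
}

#' Fit steady-state SPR affinity (1:1 equilibrium model)
#'
#' Least squares of `Req = Rmax C / (KD + C)` to an equilibrium-response
#' dilution series. Warns (with a condition diagnostic) when the
#' concentration series does not span `KD`, in which case `KD` and `Rmax`
#' are barely identifiable.
#'
#' @param data data.frame with columns `C` (M) and `Req` (response units).
#' @return list: `KD` (M), `Rmax`, `se` (named standard errors), `fit`.
#' @export
fit_spr_kd <- function(data) {
  stopifnot(all(c("C", "Req") %in% names(data)))
  if (length(unique(data$C)) < 4)
    stop("under-determined fit: need >= 4 concentrations")
  start <- list(KD = stats::median(data$C), Rmax = max(data$Req) * 1.2)
  fit <- minpack.lm::nlsLM(Req ~ Rmax * C / (KD + C), data = data,
                           start = start,
                           lower = c(KD = 1e-15, Rmax = 1e-12))
  co <- summary(fit)$coefficients
  kd <- co["KD", "Estimate"]
  if (kd < min(data$C) / 20 || kd > max(data$C) * 20)
    warning("fitted KD lies far outside the concentration series ",
            "(condition: KD/Cmin = ", signif(kd / min(data$C), 3),
            ", KD/Cmax = ", signif(kd / max(data$C), 3),
            "); the design does not constrain it")
  list(KD = kd, Rmax = co["Rmax", "Estimate"],
       se = co[, "Std. Error"], fit = fit)
}

#' Binding free energy from an equilibrium dissociation constant
#'
#' `delta G = -RT ln(1/K) = RT ln K` with the dissociation constant `K` in
#' molar: the association constant `1/K` enters the standard relation, so a
#' sub-molar `K` (favourable binding) gives a negative free energy, zero at
#' the 1 M standard state. `R = 8.314 J mol^-1 K^-1`; result in kJ/mol.
#'
#' @param K equilibrium dissociation constant, M (> 0).
#' @param T_kelvin absolute temperature, K.
#' @return binding free energy in kJ/mol (negative for K < 1 M).
#' @export
delta_g <- function(K, T_kelvin = 298.15) {
  if (any(K <= 0)) stop("K must be positive")
  if (any(T_kelvin <= 0)) stop("temperature must be positive")
  -GAS_CONSTANT * T_kelvin * log(1 / K) / 1000
}

#' Published affinity table for the barley exo-hydrolase study system
#'
#' The measured dissociation (`KD`, SPR at 25 C) and inhibition (`Ki`,
#' rate assays at 30 C) constants for glucose, the thio-linked substrate
#' analogues, deoxy-glucose derivatives and alkyl glucosides, used as input
#' to [table1_report].
#'
#' @return data.frame with columns `ligand`, `K` (M), `source`
#'   (`"SPR"` or `"inhibition"`).
#' @export
hvexoi_affinities <- function() {
  data.frame(
    ligand = c("Glc", "G6SG-OMe", "3dGlc", "4dGlc",
               "octyl-O-Glc", "octyl-S-Glc", "G2SG-OMe"),
    K = c(0.16e-3, 0.008e-3, 9.8e-3, 9.4e-3, 0.13e-3, 1.1e-3, 2.55e-3),
    source = c("SPR", "SPR", "inhibition", "inhibition",
               "inhibition", "inhibition", "inhibition"),
    stringsAsFactors = FALSE)
}

#' Affinity report: free energies and fold ratios
#'
#' Converts a table of equilibrium constants to binding free energies, with
#' the measurement temperature chosen per source: SPR rows at 298.15 K
#' (25 C), inhibition rows at 303.15 K (30 C). Also reports the matrix of
#' pairwise affinity fold-ratios `K_row / K_col` rounded to 2 significant
#' figures.
#'
#' @param entries data.frame with columns `ligand`, `K` (M), `source` in
#'   `{"SPR", "inhibition"}` (e.g. [hvexoi_affinities()]).
#' @return list: `table` (ligand, K, source, T_kelvin, delta_g in kJ/mol),
#'   `fold_ratios` (named square matrix, 2 s.f.).
#' @export
table1_report <- function(entries = hvexoi_affinities()) {
  stopifnot(nrow(entries) >= 1,
            all(c("ligand", "K", "source") %in% names(entries)))
  bad <- setdiff(unique(entries$source), c("SPR", "inhibition"))
  if (length(bad) > 0)
    stop("unknown source tag(s): ", paste(bad, collapse = ", "))
  Tk <- ifelse(entries$source == "SPR", 298.15, 303.15)
  tab <- data.frame(ligand = entries$ligand, K = entries$K,
                    source = entries$source, T_kelvin = Tk,
                    delta_g = delta_g(entries$K, Tk),
                    stringsAsFactors = FALSE)
  fr <- signif(outer(entries$K, entries$K, `/`), 2)
  dimnames(fr) <- list(entries$ligand, entries$ligand)
  list(table = tab, fold_ratios = fr)
}
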