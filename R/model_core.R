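#' Model parameters for the specialist-generalist competition model
#'
#' Bundles every parameter of the two-resource, two-consumer competition
#' model for a single scenario: two consumers of equal body mass `b`, one a
#' dietary specialist feeding on resource 1 only, the other a generalist
#' feeding on both resources at a reduced relative rate `alpha`. Mortality
#' is the product of home range `b^k` and an S-shaped per-unit-area death
#' rate controlled by `beta` and `gamma`. Defaults are the reference
#' parameterization used throughout the package.
#'
#' Time, resource and abundance units are arbitrary; body mass is in grams.
#'
#' @param b Body mass in grams, shared by both consumers. Accepted on
#'   `[0.1, 1e8]`; a warning is issued outside the empirical mammalian range
#'   `[1.75, 3.9e6]` g.
#' @param k1,k2 Home-range allometric exponents of the specialist and
#'   generalist. The specialist's slope is steeper: `k1 > k2`.
#' @param alpha Generalist's relative resource-acquisition rate, in (0, 1).
#' @param g Specialist per-capita resource acquisition rate.
#' @param kappa_mode Conversion-efficiency form: `"constant"` or
#'   `"allometric"` (see [conversion_efficiency()]).
#' @param kappa Constant conversion efficiency (offspring per resource);
#'   used when `kappa_mode = "constant"`.
#' @param C0,b0,C1,b1 Constants of the allometric conversion-efficiency
#'   form; required when `kappa_mode = "allometric"`. No canonical values
#'   are pinned by the package; users must supply their own.
#' @param beta,gamma Positive shape parameters of the per-unit-area
#'   mortality function (see [per_area_mortality()]).
#' @param R1,R2 Replenishment rates of resources 1 (shared) and 2
#'   (generalist-only); non-negative.
#'
#' @return An object of class `"cr_params"` (a named list).
#' @examples
#' p <- model_params(b = 100)
#' specialist_equilibrium_frequency(p)
#' @export
model_params <- function(b,
                         k1 = 0.9, k2 = 0.7,
                         alpha = 0.2, g = 1,
                         kappa_mode = c("constant", "allometric"),
                         kappa = 100,
                         C0 = NULL, b0 = NULL, C1 = NULL, b1 = NULL,
                         beta = 0.25, gamma = 100,
                         R1 = 1, R2 = 0.5) {
  kappa_mode <- match.arg(kappa_mode)
  stopifnot(is.numeric(b), length(b) == 1, is.finite(b))
  if (b <= 0) stop("body mass `b` must be positive", call. = FALSE)
  if (b < 1e-1 || b > 1e8)
    stop("body mass `b` outside the supported range [0.1, 1e8] g", call. = FALSE)
  if (b < 1.75 || b > 3.9e6)
    warning("body mass `b` outside the empirical mammalian range [1.75, 3.9e6] g",
            call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  if (!(k1 > k2))
    stop("home-range exponents must satisfy k1 > k2 (steeper specialist slope)",
         call. = FALSE)
  if (beta <= 0 || gamma <= 0) stop("`beta` and `gamma` must be positive", call. = FALSE)
  if (R1 < 0 || R2 < 0) stop("`R1` and `R2` must be non-negative", call. = FALSE)
  if (g <= 0) stop("`g` must be positive", call. = FALSE)
  if (kappa_mode == "constant" && !(is.numeric(kappa) && kappa > 0))
    stop("`kappa` must be positive in constant mode", call. = FALSE)
  if (kappa_mode == "allometric" &&
      (is.null(C0) || is.null(b0) || is.null(C1) || is.null(b1)))
    stop("allometric kappa requires C0, b0, C1 and b1", call. = FALSE)

  structure(
    list(b = b, k1 = k1, k2 = k2, alpha = alpha, g = g,
         kappa_mode = kappa_mode, kappa = kappa,
         C0 = C0, b0 = b0, C1 = C1, b1 = b1,
         beta = beta, gamma = gamma, R1 = R1, R2 = R2),
    class = "cr_params")
}

#' @export
print.cr_params <- function(x, ...) {
  cat("<cr_params> specialist-generalist competition parameters\n")
  cat(sprintf("  b = %g g, k1 = %g, k2 = %g, alpha = %g, g = %g\n",
              x$b, x$k1, x$k2, x$alpha, x$g))
  if (x$kappa_mode == "constant") {
    cat(sprintf("  kappa = %g (constant)\n", x$kappa))
  } else {
    cat(sprintf("  kappa allometric: C0 = %g, b0 = %g, C1 = %g, b1 = %g\n",
                x$C0, x$b0, x$C1, x$b1))
  }
  cat(sprintf("  beta = %g, gamma = %g, R1 = %g, R2 = %g\n",
              x$beta, x$gamma, x$R1, x$R2))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, revalidated through
#' [model_params()].
#'
#' @param p A `"cr_params"` object.
#' @param ... Named fields to replace (e.g. `b = 300`, `alpha = 0.1`).
#' @return A `"cr_params"` object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "cr_params"))
  new <- list(...)
  unknown <- setdiff(names(new), names(p))
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  fields <- unclass(p)
  fields[names(new)] <- new
  do.call(model_params, fields)
}

#' Home-range size as a power law of body mass
#'
#' Home range scales allometrically with body mass, `h = b^k`, with a
#' steeper exponent for specialists than generalists.
#'
#' @param b Body mass in grams (positive; vectorized).
#' @param k Allometric exponent.
#' @return Home-range size (dimensionless units).
#' @examples
#' home_range(100, 0.9)  # 10^1.8
#' @export
home_range <- function(b, k) {
  if (any(b <= 0)) stop("body mass must be positive", call. = FALSE)
  b^k
}

#' Per-unit-area mortality rate
#'
#' An S-shaped, monotonically decreasing function of body mass,
#' `d(b) = 1 - exp(-gamma * exp(-b^beta))`, bounded in (0, 1): small-bodied
#' animals suffer high per-area external mortality (e.g. predation), very
#' large ones almost none.
#'
#' @param b Body mass in grams (positive; vectorized).
#' @param beta,gamma Positive shape parameters: `beta` sets how fast the
#'   decline sets in along the mass axis, `gamma` the small-body plateau.
#' @return Death rate per unit area, in (0, 1).
#' @export
per_area_mortality <- function(b, beta, gamma) {
  if (any(b <= 0)) stop("body mass must be positive", call. = FALSE)
  if (beta <= 0 || gamma <= 0) stop("beta and gamma must be positive", call. = FALSE)
  # -expm1 keeps precision when gamma * exp(-b^beta) is tiny (huge b):
  # the death rate then equals that product instead of rounding to 0
  -expm1(-gamma * exp(-b^beta))
}

#' Per-capita mortality rate of a consumer
#'
#' Mortality is the product of home range and per-unit-area death rate,
#' `m_i = b^{k_i} d(b)`. Because `k1 > k2`, the specialist's mortality
#' exceeds the generalist's for `b > 1`.
#'
#' @param p A `"cr_params"` object.
#' @param which `"specialist"` or `"generalist"`.
#' @return Per-capita mortality rate (per unit time).
#' @export
mortality_rate <- function(p, which = c("specialist", "generalist")) {
  stopifnot(inherits(p, "cr_params"))
  which <- match.arg(which)
  k <- if (which == "specialist") p$k1 else p$k2
  home_range(p$b, k) * per_area_mortality(p$b, p$beta, p$gamma)
}

#' Conversion efficiency from resource to offspring
#'
#' Either a constant `kappa`, or a body-mass-dependent harmonic-mean form
#' `kappa(b) = C0 b^{b0} C1 b^{b1} / (C0 b^{b0} + C1 b^{b1})`. The form
#' affects transient dynamics only, never the equilibrium specialist
#' frequency, because both equal-sized consumers share the same `kappa`.
#'
#' @param p A `"cr_params"` object.
#' @return Conversion efficiency (offspring per resource).
#' @export
conversion_efficiency <- function(p) {
  stopifnot(inherits(p, "cr_params"))
  if (p$kappa_mode == "constant") return(p$kappa)
  t0 <- p$C0 * p$b^p$b0
  t1 <- p$C1 * p$b^p$b1
  t0 * t1 / (t0 + t1)
}

# internal: precompute rates reused across the module
derived_rates <- function(p) {
  list(m1 = mortality_rate(p, "specialist"),
       m2 = mortality_rate(p, "generalist"),
       kappa = conversion_efficiency(p))
}

#' Right-hand side of the competition ODE system
#'
#' Rates of change of the two resources and two consumers:
#' \deqn{dr_1/dt = R_1 - g r_1 x_1 - \alpha g r_1 x_2}
#' \deqn{dr_2/dt = R_2 - \alpha g r_2 x_2}
#' \deqn{dx_1/dt = \kappa g r_1 x_1 - m_1 x_1}
#' \deqn{dx_2/dt = \kappa \alpha g (r_1 + r_2) x_2 - m_2 x_2}
#'
#' @param state Named numeric vector with components `r1`, `r2`, `x1`, `x2`
#'   (non-negative).
#' @param p A `"cr_params"` object.
#' @return Named numeric vector of rates `(dr1, dr2, dx1, dx2)`.
#' @export
ode_rhs <- function(state, p) {
  stopifnot(inherits(p, "cr_params"))
  r1 <- state[["r1"]]; r2 <- state[["r2"]]
  x1 <- state[["x1"]]; x2 <- state[["x2"]]
  dr <- derived_rates(p)
  c(dr1 = p$R1 - p$g * r1 * x1 - p$alpha * p$g * r1 * x2,
    dr2 = p$R2 - p$alpha * p$g * r2 * x2,
    dx1 = dr$kappa * p$g * r1 * x1 - dr$m1 * x1,
    dx2 = dr$kappa * p$alpha * p$g * (r1 + r2) * x2 - dr$m2 * x2)
}

new_equilibrium <- function(kind, r1, r2, x1, x2, m1, m2, exists = TRUE) {
  tot <- x1 + x2
  structure(
    list(kind = kind,
         r1_star = r1, r2_star = r2, x1_star = x1, x2_star = x2,
         f_star = if (tot > 0) x1 / tot else 0,
         m1 = m1, m2 = m2, exists = exists, stable = NA),
    class = "cr_equilibrium")
}

#' @export
print.cr_equilibrium <- function(x, ...) {
  cat(sprintf("<cr_equilibrium> kind = %s%s\n", x$kind,
              if (!x$exists) " (does not exist: x1* <= 0)" else ""))
  cat(sprintf("  r1* = %.6g, r2* = %.6g, x1* = %.6g, x2* = %.6g\n",
              x$r1_star, x$r2_star, x$x1_star, x$x2_star))
  cat(sprintf("  specialist frequency f* = %.6g; stable = %s\n",
              x$f_star, x$stable))
  invisible(x)
}

#' Generalist-only equilibrium
#'
#' The boundary equilibrium at which the specialist is extinct and the
#' generalist alone consumes both resources:
#' `r1 = R1 m2 / (alpha g kappa (R1 + R2))`,
#' `r2 = R2 m2 / (alpha g kappa (R1 + R2))`,
#' `x2 = kappa (R1 + R2) / m2`.
#'
#' @param p A `"cr_params"` object with `R1 + R2 > 0`.
#' @return A `"cr_equilibrium"` with `kind = "generalist-only"`,
#'   `x1_star = 0` and `f_star = 0`.
#' @export
generalist_only_equilibrium <- function(p) {
  stopifnot(inherits(p, "cr_params"))
  dr <- derived_rates(p)
  if (p$R1 + p$R2 <= 0) stop("requires R1 + R2 > 0", call. = FALSE)
  if (dr$m2 <= 0) stop("degenerate parameters: generalist mortality m2 = 0",
                       call. = FALSE)
  denom <- p$alpha * p$g * dr$kappa * (p$R1 + p$R2)
  new_equilibrium("generalist-only",
                  r1 = p$R1 * dr$m2 / denom,
                  r2 = p$R2 * dr$m2 / denom,
                  x1 = 0,
                  x2 = dr$kappa * (p$R1 + p$R2) / dr$m2,
                  m1 = dr$m1, m2 = dr$m2)
}

#' Coexistence equilibrium
#'
#' The interior equilibrium at which the specialist and generalist coexist:
#' `r1* = m1/(g kappa)`, `r2* = (m2/alpha - m1)/(g kappa)`,
#' `x1* = kappa R1/m1 - kappa R2/(m2/alpha - m1)`,
#' `x2* = kappa R2 / (alpha (m2/alpha - m1))`. The equilibrium exists (has
#' `x1* > 0`) exactly when [coexistence_condition()] holds; otherwise the
#' returned object carries `exists = FALSE` and the raw (non-positive)
#' `x1_star` for diagnostics.
#'
#' @param p A `"cr_params"` object with `m2/alpha - m1 > 0`.
#' @return A `"cr_equilibrium"` with `kind = "coexistence"`.
#' @export
coexistence_equilibrium <- function(p) {
  stopifnot(inherits(p, "cr_params"))
  dr <- derived_rates(p)
  gap <- dr$m2 / p$alpha - dr$m1
  if (gap <= 0)
    stop("coexistence equilibrium undefined: m2/alpha - m1 <= 0", call. = FALSE)
  x1 <- dr$kappa * p$R1 / dr$m1 - dr$kappa * p$R2 / gap
  eq <- new_equilibrium("coexistence",
                        r1 = dr$m1 / (p$g * dr$kappa),
                        r2 = gap / (p$g * dr$kappa),
                        x1 = x1,
                        x2 = dr$kappa * p$R2 / (p$alpha * gap),
                        m1 = dr$m1, m2 = dr$m2,
                        exists = x1 > 0)
  eq
}

#' Does the coexistence condition hold?
#'
#' Coexistence requires a positive specialist equilibrium abundance,
#' `(R1/m1) (m2/alpha - m1) > R2`, equivalently (in allometric terms)
#' `b^{k2} R1 > alpha b^{k1} (R1 + R2)`.
#'
#' @param p A `"cr_params"` object.
#' @return `TRUE` if the specialist can persist at equilibrium.
#' @export
coexistence_condition <- function(p) {
  stopifnot(inherits(p, "cr_params"))
  p$b^p$k2 * p$R1 > p$alpha * p$b^p$k1 * (p$R1 + p$R2)
}

#' Body mass at the coexistence boundary
#'
#' Solves the coexistence condition at equality for body mass:
#' `b* = (alpha (R1 + R2) / R1)^{1/(k2 - k1)}`. With the default
#' parameterization this is about 411.5 g; the specialist persists at
#' equilibrium only below `b*`.
#'
#' @param p A `"cr_params"` object.
#' @return The boundary body mass in grams.
#' @export
coexistence_boundary_mass <- function(p) {
  stopifnot(inherits(p, "cr_params"))
  (p$alpha * (p$R1 + p$R2) / p$R1)^(1 / (p$k2 - p$k1))
}

#' Raw equilibrium specialist frequency (diagnostic)
#'
#' The closed-form equilibrium frequency
#' \deqn{f^* = \frac{b^{k_2} R_1 - \alpha b^{k_1}(R_1+R_2)}
#'                  {b^{k_2} R_1 - \alpha b^{k_1}(R_1+R_2) + b^{k_1} R_2}}
#' evaluated without truncation: negative values indicate that the
#' specialist is excluded. The shared per-area death rate `d(b)` and the
#' conversion efficiency cancel from this expression, which is why neither
#' influences the equilibrium outcome.
#'
#' @param p A `"cr_params"` object.
#' @return The untruncated equilibrium frequency (may be negative).
#' @seealso [specialist_equilibrium_frequency()]
#' @export
specialist_frequency_raw <- function(p) {
  stopifnot(inherits(p, "cr_params"))
  num <- p$b^p$k2 * p$R1 - p$alpha * p$b^p$k1 * (p$R1 + p$R2)
  num / (num + p$b^p$k1 * p$R2)
}

#' Equilibrium specialist frequency
#'
#' The specialist's share of total consumer abundance at equilibrium:
#' the closed-form value where the coexistence condition holds, and exactly
#' 0 where it fails (the specialist goes extinct).
#'
#' @param p A `"cr_params"` object.
#' @return A frequency in `[0, 1]`.
#' @examples
#' specialist_equilibrium_frequency(model_params(b = 100))  # ~0.164
#' @export
specialist_equilibrium_frequency <- function(p) {
  if (!coexistence_condition(p)) return(0)
  max(0, specialist_frequency_raw(p))
}

#' Analytic Jacobian of the competition system
#'
#' Closed-form 4x4 Jacobian of [ode_rhs()] with respect to
#' `(r1, r2, x1, x2)`, evaluated at an arbitrary state. Analytic partials
#' avoid finite-difference step-size fragility across seven orders of
#' magnitude of body mass.
#'
#' @param p A `"cr_params"` object.
#' @param state Named numeric vector `(r1, r2, x1, x2)`.
#' @return A 4x4 numeric matrix with dimnames `r1, r2, x1, x2`.
#' @export
jacobian_matrix <- function(p, state) {
  stopifnot(inherits(p, "cr_params"))
  r1 <- state[["r1"]]; r2 <- state[["r2"]]
  x1 <- state[["x1"]]; x2 <- state[["x2"]]
  dr <- derived_rates(p)
  ag <- p$alpha * p$g
  kg <- dr$kappa * p$g
  J <- matrix(0, 4, 4, dimnames = list(c("r1", "r2", "x1", "x2"),
                                       c("r1", "r2", "x1", "x2")))
  J["r1", ] <- c(-p$g * x1 - ag * x2, 0, -p$g * r1, -ag * r1)
  J["r2", ] <- c(0, -ag * x2, 0, -ag * r2)
  J["x1", ] <- c(kg * x1, 0, kg * r1 - dr$m1, 0)
  J["x2", ] <- c(dr$kappa * ag * x2, dr$kappa * ag * x2, 0,
                 dr$kappa * ag * (r1 + r2) - dr$m2)
  J
}

#' Local stability of an equilibrium from Jacobian eigenvalues
#'
#' Verifies that the supplied state annihilates [ode_rhs()] (to a relative
#' tolerance), then classifies local stability from the eigenvalues of the
#' analytic Jacobian: stable iff all real parts are negative.
#'
#' @param p A `"cr_params"` object.
#' @param eq A `"cr_equilibrium"` or a named state vector `(r1, r2, x1, x2)`.
#' @param tol Equilibrium tolerance: maximum `|rate|` allowed, relative to
#'   `max(1, abundance scale)`.
#' @return A list with `eigenvalues` (complex, length 4) and `stable`
#'   (logical).
#' @export
jacobian_stability <- function(p, eq, tol = 1e-9) {
  stopifnot(inherits(p, "cr_params"))
  state <- if (inherits(eq, "cr_equilibrium")) {
    c(r1 = eq$r1_star, r2 = eq$r2_star, x1 = eq$x1_star, x2 = eq$x2_star)
  } else {
    eq[c("r1", "r2", "x1", "x2")]
  }
  rates <- ode_rhs(state, p)
  scale <- max(1, abs(state))
  if (max(abs(rates)) / scale > tol)
    stop(sprintf("state is not an equilibrium: max |rate|/scale = %.3g > %.3g",
                 max(abs(rates)) / scale, tol), call. = FALSE)
  ev <- eigen(jacobian_matrix(p, state), only.values = TRUE)$values
  list(eigenvalues = ev, stable = all(Re(ev) < 0))
}

#' The equilibrium the system settles to
#'
#' Returns the coexistence equilibrium where the coexistence condition
#' holds, and the generalist-only equilibrium otherwise, with its stability
#' classification filled in.
#'
#' @param p A `"cr_params"` object.
#' @return A `"cr_equilibrium"` with the `stable` field set.
#' @export
equilibrium_state <- function(p) {
  eq <- if (coexistence_condition(p)) coexistence_equilibrium(p)
        else generalist_only_equilibrium(p)
  eq$stable <- jacobian_stability(p, eq)$stable
  eq
}

#' Read/write a flat parameter configuration
#'
#' Parameter sets serialize as a flat `key: value` text file using the
#' canonical field names (`b`, `k1`, `k2`, `alpha`, `g`, `kappa_mode`,
#' `kappa`, `C0`, `b0`, `C1`, `b1`, `beta`, `gamma`, `R1`, `R2`). Unset
#' allometric constants are omitted.
#'
#' @param p A `"cr_params"` object.
#' @param path File path.
#' @return `write_params_config()` returns `path` invisibly;
#'   `read_params_config()` returns a `"cr_params"` object.
#' @export
write_params_config <- function(p, path) {
  stopifnot(inherits(p, "cr_params"))
  fields <- Filter(Negate(is.null), unclass(p))
  lines <- vapply(names(fields), function(nm) {
    v <- fields[[nm]]
    val <- if (is.character(v)) v else format(v, digits = 17)
    paste0(nm, ": ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), character(1))
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = ":"))
    if (v %in% c("constant", "allometric")) v else as.numeric(v)
  })
  names(vals) <- keys
  do.call(model_params, vals)
}
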