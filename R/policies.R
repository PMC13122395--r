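#' Treatment policies for longitudinal exposures
#'
#' A policy describes one side of a causal contrast: what the exposure process
#' would look like under intervention.  Four kinds are supported:
#'
#' * `identity` — the natural course; exposures are left as observed.
#' * `set_all` — a deterministic policy assigning every participant the same
#'   exposure `value` at every intervention wave (e.g. "everyone attends",
#'   "everyone stops").
#' * `ips_shift` — an incremental propensity score intervention with intensity
#'   `delta` > 1 for a binary exposure: each participant's conditional
#'   probability of *not* initiating is divided by `delta`, so an observed
#'   initiation probability `p` becomes `1 - (1 - p) / delta`.
#' * `additive_shift` — a modified treatment policy for a continuous exposure:
#'   the observed exposure is increased by `shift_amount`, except that values
#'   that would exceed `support_cap` are left unchanged, so the policy never
#'   pushes exposure outside its observed support.
#'
#' Note on conventions: `delta` here divides the probability of
#' *non-initiation* (the convention this package adopts throughout), not the odds of
#' treatment as in the Kennedy-style incremental odds-multiplier.  Both
#' parameterisations appear in the literature; they agree only at
#' `delta = 1`, which is the identity policy under either convention.
#' Shifts with `delta < 1` (making initiation rarer) are rejected rather than
#' silently supported.
#'
#' @param kind One of `"identity"`, `"set_all"`, `"ips_shift"`,
#'   `"additive_shift"`.
#' @param value Exposure value forced by a `set_all` policy (0 or 1 for a
#'   binary exposure).
#' @param delta Shift intensity for `ips_shift`; must be `>= 1`.
#' @param shift_amount Additive increment for `additive_shift`, in exposure
#'   units.
#' @param support_cap Largest exposure value the additive shift may produce;
#'   defaults to the sample maximum when the policy is applied to data.
#' @return An object of class `sdr_policy`.
#' @examples
#' policy("ips_shift", delta = 5)
#' policy("set_all", value = 0)
#' parse_policy("ips:5")
#' @export
policy <- function(kind = c("identity", "set_all", "ips_shift", "additive_shift"),
                   value = NULL, delta = NULL, shift_amount = NULL,
                   support_cap = NULL) {
  kind <- match.arg(kind)
  if (kind == "set_all") {
    if (is.null(value) || length(value) != 1L || !is.finite(value)) {
      stop_sdr("sdrshift_policy_error", "set_all policy requires a single finite 'value'")
    }
  }
  if (kind == "ips_shift") {
    if (is.null(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0) {
      stop_sdr("sdrshift_policy_error", "ips_shift policy requires delta > 0")
    }
    if (delta < 1) {
      stop_sdr("sdrshift_policy_error",
               "ips_shift with delta < 1 (making initiation rarer) is not defined; use delta >= 1")
    }
  }
  if (kind == "additive_shift") {
    if (is.null(shift_amount) || !is.finite(shift_amount)) {
      stop_sdr("sdrshift_policy_error", "additive_shift policy requires a finite 'shift_amount'")
    }
  }
  structure(
    list(kind = kind, value = value, delta = delta,
         shift_amount = shift_amount, support_cap = support_cap),
    class = "sdr_policy"
  )
}

#' @export
print.sdr_policy <- function(x, ...) {
  cat("<sdr_policy> ", policy_label(x), "\n", sep = "")
  invisible(x)
}

#' Compact label for a policy
#'
#' @param x An `sdr_policy`.
#' @return A single string such as `"ips:5"` or `"set:0"`.
#' @export
policy_label <- function(x) {
  switch(x$kind,
    identity = "identity",
    set_all = paste0("set:", x$value),
    ips_shift = paste0("ips:", x$delta),
    additive_shift = paste0("add:", x$shift_amount,
                            if (!is.null(x$support_cap)) paste0("@cap=", x$support_cap) else "")
  )
}

#' Parse a policy from its string form
#'
#' Accepts the grammar used in configuration files: `identity`, `set:1`,
#' `set:0`, `ips:5`, `add:1`, `add:1@cap=20`.
#'
#' @param text A single policy string.
#' @return An `sdr_policy`.
#' @export
parse_policy <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (text == "identity") return(policy("identity"))
  if (grepl("^set:", text)) {
    return(policy("set_all", value = as.numeric(sub("^set:", "", text))))
  }
  if (grepl("^ips:", text)) {
    return(policy("ips_shift", delta = as.numeric(sub("^ips:", "", text))))
  }
  if (grepl("^add:", text)) {
    body <- sub("^add:", "", text)
    parts <- strsplit(body, "@cap=", fixed = TRUE)[[1]]
    cap <- if (length(parts) == 2L) as.numeric(parts[2]) else NULL
    return(policy("additive_shift", shift_amount = as.numeric(parts[1]), support_cap = cap))
  }
  stop_sdr("sdrshift_policy_error", "cannot parse policy string '%s'", text)
}

#' Incremental propensity score shift of an initiation probability
#'
#' Divides the probability of non-initiation by `delta`: a per-wave initiation
#' probability `p` becomes `1 - (1 - p) / delta`.  With `p = 0.03` and
#' `delta = 5` the shifted probability is 0.806: when initiation is rare the
#' compression of the non-initiation probability is large, so a five-fold
#' shift describes a world in which most non-initiators would begin, not a
#' marginal nudge.  Monotone increasing in both `p` and `delta`; `delta = 1`
#' is the identity.
#'
#' @param p Probability of initiation, in `[0, 1]`.  Vectorised.
#' @param delta Shift intensity, `>= 1`.
#' @return Shifted probability in `[1 - 1/delta, 1]`.
#' @examples
#' ips_shift_probability(0.03, 5)  # 0.806
#' @export
ips_shift_probability <- function(p, delta) {
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    stop_sdr("sdrshift_policy_error", "delta must be a single positive number")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_sdr("sdrshift_policy_error", "p must lie in [0, 1]")
  }
  out <- 1 - (1 - p) / delta
  if (any(out < 0, na.rm = TRUE)) {
    stop_sdr("sdrshift_policy_error",
             "delta < 1 produced a negative shifted probability; shrinking shifts are not defined")
  }
  out
}

#' Probability mass of an exposure value under a policy
#'
#' For a binary exposure with natural propensity `g = P(A = 1 | history)`,
#' returns the probability that the policy assigns exposure value `a`.
#' Masses over `a` in `{0, 1}` sum to one.
#'
#' @param policy An `sdr_policy` (`identity`, `set_all` or `ips_shift`).
#' @param a Observed/queried exposure value(s), 0 or 1.  Vectorised with `g`.
#' @param g Natural propensity `P(A = 1 | history)`, in `(0, 1)` for
#'   `ips_shift`.
#' @return Probability mass of `a` under the policy.
#' @export
policy_probability <- function(policy, a, g) {
  stopifnot(inherits(policy, "sdr_policy"))
  if (policy$kind == "additive_shift") {
    stop_sdr("sdrshift_policy_error",
             "policy_probability is defined for binary-exposure policies only")
  }
  if (any(!(a %in% c(0, 1)) & !is.na(a))) {
    stop_sdr("sdrshift_policy_error", "binary policies require exposure values in {0, 1}")
  }
  switch(policy$kind,
    identity = ifelse(a == 1, g, 1 - g),
    set_all = {
      if (!(policy$value %in% c(0, 1))) {
        stop_sdr("sdrshift_policy_error",
                 "set_all value %s does not match a binary exposure domain", policy$value)
      }
      as.numeric(a == policy$value)
    },
    ips_shift = {
      p_shift <- ips_shift_probability(g, policy$delta)
      ifelse(a == 1, p_shift, 1 - p_shift)
    }
  )
}

#' Density ratio of a policy at an observed exposure
#'
#' The ratio of the policy-implied exposure mass to the observed exposure mass
#' given history: `policy_probability(policy, a, g) / (g if a = 1 else 1 - g)`.
#' Ratios near 1 indicate the policy asks little of the data; ratios near 0
#' indicate the intervention requires extrapolation.  For an `ips_shift`
#' policy the ratio at `a = 0` is exactly `1/delta`; at `a = 1` it is
#' `(1 - (1 - g)/delta) / g`.  When `g` is the true propensity the ratio has
#' expectation 1 over the observed exposure distribution.
#'
#' @inheritParams policy_probability
#' @return Nonnegative density ratio, vectorised over `a` and `g`.
#' @export
density_ratio <- function(policy, a, g) {
  stopifnot(inherits(policy, "sdr_policy"))
  obs_mass <- ifelse(a == 1, g, 1 - g)
  if (policy$kind == "set_all" && any(obs_mass == 0 & !is.na(obs_mass))) {
    stop_sdr("sdrshift_positivity_error",
             "observed exposure has zero probability under the fitted propensity; positivity violated")
  }
  policy_probability(policy, a, g) / obs_mass
}

#' Apply an additive shift to a continuous exposure
#'
#' Returns `a + shift_amount`, except that values which would exceed the
#' policy's `support_cap` are returned unchanged, restricting the shift to the
#' observed support of the exposure.
#'
#' @param policy An `sdr_policy` of kind `additive_shift`.
#' @param a Observed continuous exposure value(s).
#' @return Shifted exposure values.
#' @examples
#' pol <- policy("additive_shift", shift_amount = 1, support_cap = 20)
#' apply_additive_shift(pol, c(3, 20))  # 4, 20
#' @export
apply_additive_shift <- function(policy, a) {
  stopifnot(inherits(policy, "sdr_policy"))
  if (policy$kind != "additive_shift") {
    stop_sdr("sdrshift_policy_error", "apply_additive_shift requires an additive_shift policy")
  }
  shifted <- a + policy$shift_amount
  if (!is.null(policy$support_cap)) {
    shifted <- ifelse(shifted > policy$support_cap, a, shifted)
  }
  shifted
}
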