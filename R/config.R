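#' Session configuration
#'
#' Builds a validated configuration object describing one behavioral session
#' of the automated dyadic lever-pulling task. Two reward contingencies
#' exist:
#' \describe{
#'   \item{\code{self_reward}}{each animal's lever pull independently earns
#'     that animal a small liquid reward (default 0.1 ml) at pull time.}
#'   \item{\code{mutual_cooperation}}{a pull pair by the two animals within
#'     the cooperation window triggers a tone at the follower's pull time
#'     and delivers a larger reward (default 0.2 ml) to \emph{both} animals
#'     after a fixed delay (default 1 s).}
#' }
#' The cooperation window is typically staircased during training through
#' 3 s, 2 s, 1.5 s down to the final 1 s stage; any positive value is
#' accepted.
#'
#' @param condition `"self_reward"` or `"mutual_cooperation"`.
#' @param coop_window_ms Maximum leader-to-follower latency (ms) for a pull
#'   pair to count as successful cooperation. Default 1000.
#' @param position_threshold Lever position (angular units) that a pull must
#'   reach to register. Default 1.
#' @param rearm_fraction After a registered pull the lever must return below
#'   `rearm_fraction * position_threshold` before another pull can register
#'   (hysteresis). In (0, 1); default 0.5.
#' @param reward_volume_self_ml Reward volume per pull in the self-reward
#'   condition (ml). Default 0.1.
#' @param reward_volume_coop_ml Reward volume per animal per successful
#'   cooperation (ml). Default 0.2.
#' @param reward_delay_coop_ms Delay from follower pull to cooperative
#'   reward delivery (ms). Default 1000.
#' @param pull_force_g Force (grams) the animal must exert; documentation
#'   only — pull detection uses position. Typical values 50 (shaping) and
#'   100 (final). Default 100.
#' @param session_duration_ms Session length in ms. Default 20 minutes.
#' @param sample_rate_hz Lever sampling rate (Hz). Default 1000 (millisecond
#'   resolution).
#' @param rng_seed Integer seed recorded with the session.
#' @param leader_preference When several unmatched opposite-actor pulls lie
#'   within the window, pair with the `"earliest"` (default, causal
#'   first-come-first-served) or `"latest"` one.
#' @param lockout_ms Optional refractory period after a reward during which
#'   pulls are ignored; the task is normally completely unconstrained, so
#'   the default is 0.
#'
#' @return An object of class `session_config` (a named list).
#' @examples
#' cfg <- session_config("mutual_cooperation", coop_window_ms = 1000)
#' cfg$reward_volume_coop_ml
#' @export
session_config <- function(condition = c("self_reward", "mutual_cooperation"),
                           coop_window_ms = 1000L,
                           position_threshold = 1,
                           rearm_fraction = 0.5,
                           reward_volume_self_ml = 0.1,
                           reward_volume_coop_ml = 0.2,
                           reward_delay_coop_ms = 1000L,
                           pull_force_g = 100,
                           session_duration_ms = 1200000L,
                           sample_rate_hz = 1000,
                           rng_seed = 1L,
                           leader_preference = c("earliest", "latest"),
                           lockout_ms = 0L) {
  condition <- match.arg(condition)
  leader_preference <- match.arg(leader_preference)
  cfg <- structure(list(
    condition = condition,
    coop_window_ms = as.integer(coop_window_ms),
    position_threshold = as.numeric(position_threshold),
    rearm_fraction = as.numeric(rearm_fraction),
    reward_volume_self_ml = as.numeric(reward_volume_self_ml),
    reward_volume_coop_ml = as.numeric(reward_volume_coop_ml),
    reward_delay_coop_ms = as.integer(reward_delay_coop_ms),
    pull_force_g = as.numeric(pull_force_g),
    session_duration_ms = as.integer(session_duration_ms),
    sample_rate_hz = as.numeric(sample_rate_hz),
    rng_seed = as.integer(rng_seed),
    leader_preference = leader_preference,
    lockout_ms = as.integer(lockout_ms)
  ), class = "session_config")
  validate_session_config(cfg)
}

#' Validate a session configuration
#'
#' @param cfg A `session_config` (or plain named list with the same fields).
#' @return The validated `session_config`, invisibly usable in pipelines.
#' @export
validate_session_config <- function(cfg) {
  if (!is.list(cfg)) validation_error("config must be a list")
  req <- c("condition", "coop_window_ms", "position_threshold",
           "rearm_fraction", "reward_volume_self_ml", "reward_volume_coop_ml",
           "reward_delay_coop_ms", "session_duration_ms", "sample_rate_hz")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    validation_error("config missing fields: ", paste(miss, collapse = ", "))
  if (!cfg$condition %in% c("self_reward", "mutual_cooperation"))
    validation_error("unknown condition: ", cfg$condition)
  stopifnot_scalar_num(cfg$coop_window_ms, "coop_window_ms", lower = 0,
                       open_lower = TRUE)
  stopifnot_scalar_num(cfg$rearm_fraction, "rearm_fraction", lower = 0,
                       upper = 1, open_lower = TRUE, open_upper = TRUE)
  stopifnot_scalar_num(cfg$reward_volume_self_ml, "reward_volume_self_ml",
                       lower = 0)
  stopifnot_scalar_num(cfg$reward_volume_coop_ml, "reward_volume_coop_ml",
                       lower = 0)
  stopifnot_scalar_num(cfg$reward_delay_coop_ms, "reward_delay_coop_ms",
                       lower = 0)
  stopifnot_scalar_num(cfg$session_duration_ms, "session_duration_ms",
                       lower = 0, open_lower = TRUE)
  stopifnot_scalar_num(cfg$sample_rate_hz, "sample_rate_hz", lower = 0,
                       open_lower = TRUE)
  if (!is.null(cfg$lockout_ms))
    stopifnot_scalar_num(cfg$lockout_ms, "lockout_ms", lower = 0)
  class(cfg) <- "session_config"
  cfg
}

#' Read / write a session configuration as YAML
#'
#' Serialization round-trips losslessly: `read_session_config(
#' write_session_config(cfg, f))` equals `cfg`.
#'
#' @param path File path of the YAML configuration.
#' @return `read_session_config` returns a validated `session_config`;
#'   `write_session_config` returns `path` invisibly.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) format_error("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    format_error("cannot parse YAML config '", path, "': ", conditionMessage(e)))
  defaults <- session_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    validation_error("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(unclass(defaults), raw)
  # integer-typed fields
  for (f in c("coop_window_ms", "reward_delay_coop_ms", "session_duration_ms",
              "rng_seed", "lockout_ms"))
    cfg[[f]] <- as.integer(cfg[[f]])
  validate_session_config(cfg)
}

#' @rdname read_session_config
#' @param cfg A `session_config`.
#' @export
write_session_config <- function(cfg, path) {
  cfg <- validate_session_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config> condition =", x$condition, "\n")
  cat("  coop_window_ms:", x$coop_window_ms,
      "| threshold:", x$position_threshold,
      "| rearm:", x$rearm_fraction, "\n")
  cat("  rewards: self", x$reward_volume_self_ml, "ml; coop",
      x$reward_volume_coop_ml, "ml @ +", x$reward_delay_coop_ms, "ms\n")
  cat("  duration:", x$session_duration_ms, "ms @", x$sample_rate_hz, "Hz\n")
  invisible(x)
}
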