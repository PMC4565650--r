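# Shared fixtures, built in code: the shipped default parameter set, a
# fully balanced variant (NEFA flux zero at the fasting state) and a
# decoupled variant (no NEFA action on glucose fluxes).

default_p <- default_parameters()

# NEFA equation balanced at basal: dNEFA/dt(0) = 0
balanced_p <- balance_nefa(default_p)

# NEFA coupling to glucose disabled: kegp5 = 0, NEFA-independent Vmax
# (kuid1 re-derived so the glucose subsystem stays at its fixed point)
decoupled_p <- balance_nefa(default_parameters(
  free = list(kegp5 = 0, kuid3 = 0, kuid1 = NA_real_)))

# random valid parameter set: free parameters log-jittered around defaults
random_params <- function() {
  fr <- default_p$free
  jitter <- 10^stats::runif(length(fr), -0.3, 0.3)
  fr2 <- fr * ifelse(names(fr) == "pC", 1, jitter)
  fr2[["pC"]] <- -abs(fr[["pC"]]) * jitter[[which(names(fr) == "pC")]]
  default_parameters(free = as.list(fr2))
}

# random-but-plausible state around the basal point
random_state <- function(params) {
  st <- basal_state(params)
  st * stats::runif(length(st), 0.5, 1.5) + 1e-3
}

# small clamp-only dataset whose observed values are the model's own
# predictions (perfect fit by construction)
perfect_fit_dataset <- function(params, se = c(0.1, 0.2)) {
  protos <- clamp1_design(params)[c(1, 3)]
  obs <- do.call(rbind, lapply(names(protos), function(pid) {
    r <- simulate_clamp(protos[[pid]], params, dt = 2)
    data.frame(protocol_id = pid, observable = c("EGP_avg", "GU_avg"),
               time = NA_real_, value = c(r$EGP_avg, r$GU_avg),
               se = se, source = "synthetic")
  }))
  dataset(obs, protos)
}
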