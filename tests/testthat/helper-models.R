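# Small fixture models built in code.

# Alive/Dead chain with constant per-cycle death probability and an
# end-of-cycle survival reward; life expectancy has the geometric
# closed form sum_{t=1..n} (1 - p)^t.
two_state_chain <- function(p_die = 0.01, n_cycles = 5,
                            channels = c("survival", "utility")) {
  P <- rbind(Alive = c(1 - p_die, p_die), Dead = c(0, 1))
  colnames(P) <- c("Alive", "Dead")
  model <- transition_model(c("Alive", "Dead"), P, n_cycles,
                            absorbing = "Dead")
  R <- reward_array(c("Alive", "Dead"), channels, 1)
  R["Alive", , 1] <- 1
  rewards <- reward_schedule(R, death_cycle_fraction = 0,
                             death_credit_channels = character())
  list(model = model, rewards = rewards,
       initial = c(Alive = 1, Dead = 0))
}

# Irreducible-ish three-state chain with heterogeneous rewards on two
# channels, used for cohort-vs-microsim oracle checks.
three_state_chain <- function(n_cycles = 4) {
  states <- c("A", "B", "Dead")
  P <- rbind(A = c(0.7, 0.25, 0.05),
             B = c(0.1, 0.8, 0.1),
             Dead = c(0, 0, 1))
  colnames(P) <- states
  model <- transition_model(states, P, n_cycles, absorbing = "Dead")
  R <- reward_array(states, c("utility", "cost"), 1)
  R["A", , 1] <- c(0.9, 100)
  R["B", , 1] <- c(0.6, 250)
  tr <- lapply(seq_len(n_cycles), function(t) {
    m <- matrix(0, 3, 3, dimnames = list(states, states))
    m["A", "B"] <- 40  # one-off event cost on the A -> B transition
    list(cost = m)
  })
  rewards <- reward_schedule(R, tr, death_cycle_fraction = 0.5,
                             death_credit_channels = "utility")
  list(model = model, rewards = rewards,
       initial = c(A = 0.6, B = 0.4, Dead = 0))
}

# asthma parameters with every death hazard switched off
asthma_params_no_death <- function(...) {
  asthma_params(p_death_er = 0, p_death_admit = 0, p_death_other = 0,
                ...)
}
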