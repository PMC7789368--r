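# Build valid district rows in code; every field overridable.
make_district <- function(district_id = "S01-D001",
                          state_id = "S01",
                          hcc = c(1L, 1L),
                          n_subdistricts = length(hcc),
                          n_neighborhoods = 3L * n_subdistricts,
                          population_total = 1000,
                          insured_total = 400,
                          insured_poor = 150,
                          insured_rich = 250,
                          visits_total = 500,
                          visits_poor = 200,
                          visits_rich = 300,
                          cost_local = 7000,
                          income_data_present = TRUE) {
  tibble::tibble(
    state_id = state_id, district_id = district_id,
    n_subdistricts = as.integer(n_subdistricts),
    n_neighborhoods = as.integer(n_neighborhoods),
    population_total = population_total, insured_total = insured_total,
    insured_poor = insured_poor, insured_rich = insured_rich,
    hcc_counts = list(as.integer(hcc)),
    visits_total = visits_total, visits_poor = visits_poor,
    visits_rich = visits_rich, cost_local = cost_local,
    income_data_present = income_data_present
  )
}

# Random valid district (for property-style tests); caller controls the seed.
random_district <- function(id) {
  n_sub <- sample(1:5, 1)
  insured <- sample(50:5000, 1)
  poor <- rbinom(1, insured, 0.4)
  visits <- rpois(1, insured)
  vp <- rbinom(1, visits, 0.4)
  make_district(
    district_id = sprintf("S01-D%03d", id),
    hcc = sample(0:3, n_sub, replace = TRUE),
    n_subdistricts = n_sub,
    population_total = insured * 2,
    insured_total = insured, insured_poor = poor,
    insured_rich = insured - poor,
    visits_total = visits, visits_poor = vp, visits_rich = visits - vp
  )
}

# Independent classifier oracle: decides each rule branch from its own
# predicate, rather than the ordered case analysis the package uses.
oracle_classify <- function(hcc) {
  if (sum(hcc) == 0) return("zero")
  if (all(hcc == 1)) return("subdistrict")
  if (all(hcc >= 1) && any(hcc >= 2)) return("neighborhood")
  "district"
}

# Independent Mann-Whitney oracle: U by pair counting (not rank sums), exact
# two-sided p by enumerating every assignment of pooled values to groups.
oracle_mann_whitney_p <- function(x, y) {
  u_pairs <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  mu <- nx * (n - nx) / 2
  obs <- u_pairs(x, y)
  sets <- utils::combn(n, nx)
  u_all <- apply(sets, 2, function(ix) u_pairs(pooled[ix], pooled[-ix]))
  mean(abs(u_all - mu) >= abs(obs - mu) - 1e-9)
}
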