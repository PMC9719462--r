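# Small deterministic observation tables built in code.

make_obs <- function(n = 12, seed = 42, with_state = TRUE) {
  set.seed(seed)
  items <- matrix(sample(0:5, n * 8, replace = TRUE), n, 8,
                  dimnames = list(NULL, paste0("q", 1:8)))
  df <- data.frame(
    patient_id = paste0("P", rep(seq_len(ceiling(n / 3)), each = 3)[1:n]),
    visit = rep(1:3, length.out = n),
    age = round(runif(n, 45, 90), 1),
    sex_code = sample(0:1, n, replace = TRUE)
  )
  df <- cbind(df, items)
  if (with_state) {
    st <- matrix(sample(1:3, n * 5, replace = TRUE), n, 5,
                 dimnames = list(NULL, eq5d_dimensions()))
    df <- cbind(df, st)
    df$utility <- utility_from_state(st)
    df$stage <- sample(1:3, n, replace = TRUE)
  }
  as_observations(df)
}

# Random CAT item covariate table (no outcomes).
make_cat_rows <- function(n, seed = 1) {
  set.seed(seed)
  items <- matrix(sample(0:5, n * 8, replace = TRUE), n, 8,
                  dimnames = list(NULL, paste0("q", 1:8)))
  df <- as.data.frame(items)
  df$cat_total <- rowSums(items)
  df$age <- runif(n, 40, 95)
  df$sex_code <- sample(0:1, n, replace = TRUE)
  df
}
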