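# Independent brute-force oracle for the ACMG-AMP combining table, written
# clause by clause from the published rule list (scalar, no reuse of the
# package's vectorized implementation).

oracleCombine <- function(vs, s, m, su, ba, bsn, bpn) {
  pathogenic <- FALSE
  # (i) 1 VeryStrong AND ...
  if (vs == 1 && s >= 1) pathogenic <- TRUE              # (i)(a)
  if (vs == 1 && m >= 2) pathogenic <- TRUE              # (i)(b)
  if (vs == 1 && m == 1 && su == 1) pathogenic <- TRUE   # (i)(c)
  if (vs == 1 && su >= 2) pathogenic <- TRUE             # (i)(d)
  # (ii) >= 2 Strong
  if (s >= 2) pathogenic <- TRUE
  # (iii) 1 Strong AND ...
  if (s == 1 && m >= 3) pathogenic <- TRUE               # (iii)(a)
  if (s == 1 && m == 2 && su >= 2) pathogenic <- TRUE    # (iii)(b)
  if (s == 1 && m == 1 && su >= 4) pathogenic <- TRUE    # (iii)(c)

  likely_pathogenic <- FALSE
  if (vs == 1 && m == 1) likely_pathogenic <- TRUE       # (i)
  if (s == 1 && (m == 1 || m == 2)) likely_pathogenic <- TRUE  # (ii)
  if (s == 1 && su >= 2) likely_pathogenic <- TRUE       # (iii)
  if (m >= 3) likely_pathogenic <- TRUE                  # (iv)
  if (m == 2 && su >= 2) likely_pathogenic <- TRUE       # (v)
  if (m == 1 && su >= 4) likely_pathogenic <- TRUE       # (vi)

  benign <- (ba == 1) || (bsn >= 2)
  likely_benign <- (bsn == 1 && bpn >= 1) || (bpn >= 2)

  path_group <- pathogenic || likely_pathogenic
  benign_group <- benign || likely_benign
  if (path_group && benign_group) return("VUS")  # contradictory evidence
  if (pathogenic) return("P")
  if (likely_pathogenic) return("LP")
  if (benign) return("B")
  if (likely_benign) return("LB")
  "VUS"
}

# the exhaustive bounded tuple grid the equivalence check runs over
oracleCountGrid <- function() {
  expand.grid(vs = 0:1, s = 0:5, m = 0:7, su = 0:6,
              ba = 0:1, bsn = 0:4, bpn = 0:6,
              KEEP.OUT.ATTRS = FALSE)
}
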