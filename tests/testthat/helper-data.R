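# Case-study groups, loaded once per test session.
tab1 <- load_fixture("table1")$groups
tab1_dp <- load_fixture("table1_dprime")$groups

# Outcome-vector counts of the published frequency table for the original
# six-group analysis (used as a fixed input for tree-construction tests).
freq_fixture <- c(YYYYY = 18, YYYYN = 400, YYYNY = 39, YYYNN = 319,
                  YYNYY = 4, YYNYN = 93, YYNNY = 8, YYNNN = 29,
                  NYYYN = 35, NYYNY = 4, NYYNN = 30, NYNNN = 8, NYNYN = 13)
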