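# Default fuzzy inference configuration.
#
# Membership breakpoints are tunable defaults: PERCLOS Low/Medium and
# Medium/High crossovers at 0.15 and 0.30 (bracketing the 0.15-0.4 range of
# drowsiness thresholds reported across the behavioural-monitoring
# literature), ECD crossovers at 1 s and 4 s, AOT crossovers at 2 s and 6 s.
#
# Rule table: the cells fixed by the indicator-complementarity semantics are
#   (L,L,L)->L; (M,M,*)->M; one eye indicator H with others L -> M;
#   AOT H plus any other indicator M -> M; AOT H alone -> L;
# every remaining cell is the smallest output consistent with monotonicity,
# with High reserved for both eye indicators High, or one High plus the other
# Medium with AOT High.
variables:
  perclos:
    universe:
    - 0.0
    - 1.0
    terms:
      Low:
        shape: trapezoidal
        breakpoints:
        - 0.0
        - 0.0
        - 0.1
        - 0.2
      Medium:
        shape: trapezoidal
        breakpoints:
        - 0.1
        - 0.2
        - 0.25
        - 0.35
      High:
        shape: trapezoidal
        breakpoints:
        - 0.25
        - 0.35
        - 1.0
        - 1.0
  ecd:
    universe:
    - 0.0
    - 60.0
    terms:
      Low:
        shape: trapezoidal
        breakpoints:
        - 0.0
        - 0.0
        - 0.5
        - 1.5
      Medium:
        shape: trapezoidal
        breakpoints:
        - 0.5
        - 1.5
        - 3.0
        - 5.0
      High:
        shape: trapezoidal
        breakpoints:
        - 3.0
        - 5.0
        - 60.0
        - 60.0
  aot:
    universe:
    - 0.0
    - 60.0
    terms:
      Low:
        shape: trapezoidal
        breakpoints:
        - 0.0
        - 0.0
        - 1.0
        - 3.0
      Medium:
        shape: trapezoidal
        breakpoints:
        - 1.0
        - 3.0
        - 5.0
        - 7.0
      High:
        shape: trapezoidal
        breakpoints:
        - 5.0
        - 7.0
        - 60.0
        - 60.0
rules:
- perclos: Low
  ecd: Low
  aot: Low
  output: Low
- perclos: Medium
  ecd: Low
  aot: Low
  output: Low
- perclos: Low
  ecd: Medium
  aot: Low
  output: Low
- perclos: Medium
  ecd: Medium
  aot: Low
  output: Medium
- perclos: High
  ecd: Low
  aot: Low
  output: Medium
- perclos: Low
  ecd: High
  aot: Low
  output: Medium
- perclos: High
  ecd: Medium
  aot: Low
  output: Medium
- perclos: Medium
  ecd: High
  aot: Low
  output: Medium
- perclos: High
  ecd: High
  aot: Low
  output: High
- perclos: Low
  ecd: Low
  aot: Medium
  output: Low
- perclos: Medium
  ecd: Low
  aot: Medium
  output: Low
- perclos: Low
  ecd: Medium
  aot: Medium
  output: Low
- perclos: Medium
  ecd: Medium
  aot: Medium
  output: Medium
- perclos: High
  ecd: Low
  aot: Medium
  output: Medium
- perclos: Low
  ecd: High
  aot: Medium
  output: Medium
- perclos: High
  ecd: Medium
  aot: Medium
  output: Medium
- perclos: Medium
  ecd: High
  aot: Medium
  output: Medium
- perclos: High
  ecd: High
  aot: Medium
  output: High
- perclos: Low
  ecd: Low
  aot: High
  output: Low
- perclos: Medium
  ecd: Low
  aot: High
  output: Medium
- perclos: Low
  ecd: Medium
  aot: High
  output: Medium
- perclos: Medium
  ecd: Medium
  aot: High
  output: Medium
- perclos: High
  ecd: Low
  aot: High
  output: Medium
- perclos: Low
  ecd: High
  aot: High
  output: Medium
- perclos: High
  ecd: Medium
  aot: High
  output: High
- perclos: Medium
  ecd: High
  aot: High
  output: High
- perclos: High
  ecd: High
  aot: High
  output: High
singletons:
  Low: 0.0
  Medium: 0.5
  High: 1.0
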