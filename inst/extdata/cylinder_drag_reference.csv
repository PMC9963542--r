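# Drag coefficient of a circular cylinder in a laterally bounded uniform
# stream, confinement ratio H/D = 25 (the simulated geometry).
# Re <= 1: matched Oseen/Faxen form Cd = 8*pi / (Re * S_eff) with
#   S_eff = min(ln(7.4/Re), ln(H/D) - 0.9157)
#   (Lamb-Oseen inertial wake cutoff vs Faxen wall cutoff of the Stokes
#   logarithm, whichever screens first; Lamb 1911, Faxen 1946).
# Re = 10: Sucker & Brauer (1975) experimental correlation
#   Cd = 1.18 + 6.8/Re^0.89 + 1.96/sqrt(Re) - 0.0004 Re/(1 + 3.64e-7 Re^2)
#   (confinement negligible at this Re).
re,cd_ref
0.1,109.122
1,12.5571
10,2.67182
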