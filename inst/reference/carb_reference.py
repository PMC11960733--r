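#!/usr/bin/env python
"""Stand-alone reference carbonate-system calculator.

Given rows of (temperature degC, salinity, TA umol/kg, DIC umol/kg) on
stdin as CSV, prints CSV rows of (pH_total, pCO2_uatm). Implemented
independently of the R package (scipy root bracketing on [H+], constants
typed directly from the primary literature: Lueker et al. 2000 carbonic
acid, Dickson 1990 bisulfate and borate, Perez & Fraga 1987 fluoride,
Millero 1995 water, Weiss 1974 CO2 solubility and virial coefficients,
Uppstrom 1974 total boron) to serve as a cross-check oracle for the
package's solver.
"""
import sys
import math
import csv

from scipy.optimize import brentq


def constants(tc, s):
    tk = tc + 273.15
    lnt = math.log(tk)
    k1 = 10.0 ** -(3633.86 / tk - 61.2172 + 9.6777 * lnt
                   - 0.011555 * s + 0.0001152 * s * s)
    k2 = 10.0 ** -(471.78 / tk + 25.929 - 3.16967 * lnt
                   - 0.01781 * s + 0.0001122 * s * s)
    sq = math.sqrt(s)
    kb = math.exp((-8966.90 - 2890.53 * sq - 77.942 * s
                   + 1.728 * s ** 1.5 - 0.0996 * s * s) / tk
                  + 148.0248 + 137.1942 * sq + 1.62142 * s
                  + (-24.4344 - 25.085 * sq - 0.2474 * s) * lnt
                  + 0.053105 * sq * tk)
    kw = math.exp(148.9802 - 13847.26 / tk - 23.6521 * lnt
                  + (-5.977 + 118.67 / tk + 1.0495 * lnt) * sq
                  - 0.01615 * s)
    ion = 19.924 * s / (1000.0 - 1.005 * s)
    ks = math.exp(-4276.1 / tk + 141.328 - 23.093 * lnt
                  + (-13856.0 / tk + 324.57 - 47.986 * lnt) * math.sqrt(ion)
                  + (35474.0 / tk - 771.54 + 114.723 * lnt) * ion
                  - 2698.0 / tk * ion ** 1.5 + 1776.0 / tk * ion * ion
                  + math.log(1.0 - 0.001005 * s))
    kf = math.exp(874.0 / tk - 9.68 + 0.111 * sq)
    k0 = math.exp(-60.2409 + 93.4517 * 100.0 / tk
                  + 23.3585 * math.log(tk / 100.0)
                  + s * (0.023517 - 0.023656 * tk / 100.0
                         + 0.0047036 * (tk / 100.0) ** 2))
    bt = 0.0004157 * s / 35.0
    st = 0.02824 * s / 35.0
    ft = 0.00007 * s / 35.0
    return k0, k1, k2, kb, kw, ks, kf, bt, st, ft


def alkalinity(h, dic, k):
    k0, k1, k2, kb, kw, ks, kf, bt, st, ft = k
    d = h * h + k1 * h + k1 * k2
    hfree = h / (1.0 + st / ks)
    return (dic * (k1 * h + 2.0 * k1 * k2) / d
            + bt * kb / (kb + h) + kw / h
            - hfree - st / (1.0 + ks / hfree) - ft / (1.0 + kf / h))


def solve(tc, s, ta, dic):
    k = constants(tc, s)
    ta_m, dic_m = ta * 1e-6, dic * 1e-6
    h = brentq(lambda x: alkalinity(x, dic_m, k) - ta_m,
               1e-12, 1e-3, xtol=1e-22, rtol=8.9e-16)
    ph = -math.log10(h)
    co2 = dic_m * h * h / (h * h + k[1] * h + k[1] * k[2])
    fco2 = co2 / k[0] * 1e6
    tk = tc + 273.15
    b = -1636.75 + 12.0408 * tk - 0.0327957 * tk ** 2 + 3.16528e-5 * tk ** 3
    delta = 57.7 - 0.118 * tk
    fugfac = math.exp((b + 2.0 * delta) / (82.05736 * tk))
    return ph, fco2 / fugfac


def main():
    writer = csv.writer(sys.stdout)
    writer.writerow(["ph_total", "pco2"])
    reader = csv.reader(sys.stdin)
    header = next(reader)
    assert header[:4] == ["temperature", "salinity", "ta", "dic"], header
    for row in reader:
        tc, s, ta, dic = map(float, row[:4])
        ph, pco2 = solve(tc, s, ta, dic)
        writer.writerow([f"{ph:.8f}", f"{pco2:.5f}"])


if __name__ == "__main__":
    main()
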