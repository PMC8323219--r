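laser 0.6855 -0.2823 0.1816 0.3164 0.2021 -0.0531 0.7558 -0.0473 1.0092 -0.0314 0.6524 1.1433 -0.6944 -0.1394 -0.0667 0.3180 -0.1421 -1.3282 -1.2202 0.6601 -0.1533 -0.8907 -0.0860 0.6073 0.9476
scars -0.2152 -0.1286 -0.8816 0.2300 -0.3200 0.2277 0.3524 0.5176 -0.3045 0.2525 -0.8585 -0.3922 -0.4255 -1.2071 0.0181 0.1030 -0.1805 0.3791 -0.3634 -0.6841 0.2164 -0.4057 0.7221 -0.2157 0.3278
drusen 0.1610 -0.3919 0.7879 0.3214 0.0449 0.1383 0.3396 0.0449 -1.4965 0.1424 -0.1836 0.0926 0.2909 0.6999 -0.3636 0.6513 0.1679 0.5193 0.4604 0.3604 -0.5216 -0.0451 0.3118 -0.4768 -0.2714
cup 0.2905 0.3841 0.2319 -0.4429 -0.5499 0.7564 0.1290 0.0442 -0.0604 -0.5972 0.3060 -0.1086 -0.0914 0.4667 0.4109 0.6961 -0.2381 0.3252 0.6956 -0.5554 -0.4304 -0.5659 -0.7296 0.0400 0.3266
disc 0.6005 0.5224 -0.5016 0.9242 -0.3334 0.0528 -0.2111 -0.0612 0.0941 0.0596 -0.0125 0.0540 -0.2427 -0.2521 -0.8305 -0.1912 -0.2563 1.3509 -0.6811 0.0686 -0.7468 -0.7352 0.0624 -0.4983 -0.0009
ratio -0.2141 -0.3068 -1.0123 -0.6124 0.0898 0.2838 -0.2464 0.0000 0.5614 0.7199 -0.5486 -0.0587 0.6007 -0.2349 -0.0262 -0.0431 -0.4438 -0.2223 -0.0147 -0.2069 0.5567 -0.2405 -0.2166 0.3484 -0.5282
hemorrhages -0.0203 -0.7758 0.5836 -0.1368 -0.2339 -0.6191 -0.0039 -0.4001 -0.2667 0.6438 -0.0878 -0.5359 0.0816 -0.1814 0.2950 0.7162 -0.4963 0.2273 0.0424 0.4478 -0.1149 0.4183 -0.8725 0.8447 0.4324
retinal -0.0754 -0.7245 0.3215 0.2416 -0.0032 0.0757 -0.2921 0.1844 0.1473 -0.1396 -0.6681 0.3504 0.2771 -0.4182 -0.7973 0.1025 -0.1725 0.1263 -0.6470 -0.4796 0.5429 0.2019 0.2932 0.9076 0.0644
arteriosclerosis -1.0005 0.1669 0.5857 1.0298 -0.6884 -0.5754 -0.3529 -0.5270 -0.3229 -0.0927 -0.6006 1.0185 0.0539 -0.0421 0.2478 0.0187 -0.0660 0.7384 -0.1085 -0.6418 0.1928 -0.1758 -0.2609 -0.5341 0.2142
microaneurysms -0.0870 0.2578 -0.1172 -0.3293 0.6251 -0.1359 0.4740 -0.6008 -0.2331 -0.1347 -0.1955 0.6744 -0.0114 0.1221 -0.4712 -0.3646 0.4990 0.6292 0.6244 -0.6903 1.0250 0.5084 -0.0134 0.3518 -0.4857
hard -0.5481 0.0245 -0.5992 0.0950 0.6489 -0.5169 -0.3692 0.0233 -0.5088 -0.1916 0.4364 0.4848 0.1919 -0.9258 -0.0270 0.5324 0.4066 -0.0954 -1.3500 0.0305 0.2869 0.0229 0.0787 0.2158 -0.1983
exudates 0.6550 0.2352 -0.6213 0.6908 0.6022 0.4120 -0.8313 -0.2847 0.3178 0.0219 0.1740 1.2298 -0.4092 -1.0566 0.1368 -0.3438 0.2230 -0.4062 1.1060 -0.0619 -0.2387 -0.0831 0.4313 0.0487 -0.8128
soft -0.0023 0.3801 0.0195 0.3675 -0.0732 -0.0289 0.2412 0.4965 -0.6232 -0.0167 -0.0355 -0.3795 -0.5172 -0.3154 0.2934 -0.2082 -0.3924 0.0817 -0.6184 0.5229 -0.2423 0.0946 0.0255 -0.0001 0.9047
fundus -0.4127 0.5727 0.0158 -0.4176 -0.0344 0.3734 -0.2128 -0.3860 0.0764 0.4943 -0.0367 -0.6935 -0.6533 -0.3842 -0.2636 -0.0107 0.3352 -0.2173 -0.5569 0.3036 0.1377 0.5787 -0.8412 0.0437 0.6767
lesion 0.3621 -0.4163 0.3663 -0.4360 -0.2267 0.5938 -0.1451 0.4143 -0.1456 -0.7882 -0.4244 -0.5443 -0.2421 -0.1682 -0.0767 -0.1216 0.9461 -0.6930 -0.2074 0.1745 0.8142 0.0443 0.6196 -0.8223 0.7232
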