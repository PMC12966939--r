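Mizoram recorded the highest composite score (100.0).
Gujarat recorded the lowest composite score (0.0).
The high performance tier comprises 15 unit(s): Chandigarh, Dadra & Nagar Haveli, Daman & Diu, Goa, Himachal Pradesh, Jharkhand, Kerala, Madhya Pradesh, Manipur, Meghalaya, Mizoram, Puducherry, Punjab, Sikkim, West Bengal.
The middle performance tier comprises 14 unit(s): Andaman & Nicobar Islands, Andhra Pradesh, Assam, Chhattisgarh, Gujarat, Karnataka, Lakshadweep, Maharashtra, Nagaland, Odisha, Rajasthan, Tamil Nadu, Tripura, Uttar Pradesh.
The low performance tier comprises 8 unit(s): Arunachal Pradesh, Bihar, Delhi, Haryana, Jammu & Kashmir, Other Territories, Telangana, Uttarakhand.
There is a non-significant weak negative association between shc_functioning and phc_24x7_dlhs_3 (r = -0.02, p = 0.91).
There is a non-significant weak positive association between shc_functioning and phc_24x7_dlhs_4 (r = 0.18, p = 0.28).
There is a non-significant weak negative association between shc_functioning and anm_at_shc (r = -0.03, p = 0.84).
There is a non-significant weak positive association between shc_functioning and specialist_doctors (r = 0.05, p = 0.75).
There is a significant strong positive association between shc_functioning and phc_functioning (r = 0.53, p = 0.00).
There is a significant strong positive association between phc_24x7_dlhs_3 and phc_24x7_dlhs_4 (r = 0.66, p = 0.00).
There is a non-significant weak positive association between phc_24x7_dlhs_3 and anm_at_shc (r = 0.01, p = 0.93).
There is a non-significant weak negative association between phc_24x7_dlhs_3 and specialist_doctors (r = -0.30, p = 0.07).
There is a non-significant weak negative association between phc_24x7_dlhs_3 and phc_functioning (r = -0.02, p = 0.90).
There is a non-significant weak negative association between phc_24x7_dlhs_4 and anm_at_shc (r = -0.15, p = 0.37).
There is a non-significant moderate negative association between phc_24x7_dlhs_4 and specialist_doctors (r = -0.31, p = 0.06).
There is a non-significant weak positive association between phc_24x7_dlhs_4 and phc_functioning (r = 0.03, p = 0.88).
There is a non-significant weak positive association between anm_at_shc and specialist_doctors (r = 0.28, p = 0.09).
There is a non-significant weak negative association between anm_at_shc and phc_functioning (r = -0.09, p = 0.59).
There is a non-significant weak positive association between specialist_doctors and phc_functioning (r = 0.08, p = 0.65).
PHC 24x7 availability, DLHS-3 to DLHS-4 showed no statistically significant change (p = 0.06).
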