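unit,region
Andhra Pradesh,South
Arunachal Pradesh,North-East
Assam,North-East
Bihar,East
Chhattisgarh,Central
Goa,West
Gujarat,West
Haryana,North
Himachal Pradesh,North
Jammu & Kashmir,North
Jharkhand,East
Karnataka,South
Kerala,South
Madhya Pradesh,Central
Maharashtra,West
Manipur,North-East
Meghalaya,North-East
Mizoram,North-East
Nagaland,North-East
Odisha,East
Punjab,North
Rajasthan,North
Sikkim,North-East
Tamil Nadu,South
Telangana,South
Tripura,North-East
Uttar Pradesh,Central
Uttarakhand,North
West Bengal,East
Andaman & Nicobar Islands,Islands
Chandigarh,North
Dadra & Nagar Haveli,West
Daman & Diu,West
Delhi,North
Lakshadweep,Islands
Puducherry,South
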