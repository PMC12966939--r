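State/UT,SHC Functioning,PHC 24x7 DLHS-3 (%),PHC 24x7 DLHS-4 (%),ANM at SHC,Specialist Doctors,PHC Functioning
Andhra Pradesh,"6,575",70.1,64.6,"5,145",568,"1,521"
Arunachal Pradesh,367,27.8,39.8,"14,823",746,463
Assam,"10,175",45.9,60,"10,184",751,"1,114"
Bihar,"10,842",29,28.3,"8,836","1,098","1,323"
Chhattisgarh,"8,521",79.6,65.1,"9,979",715,"1,847"
Goa,"12,989",44.1,51.4,"12,531",754,"2,300"
Gujarat,"7,153",44.2,53.5,"4,442",0,497
Haryana,"4,537",27.5,36.5,,"1,009",949
Himachal Pradesh,"11,735",,,,559,"1,586"
Jammu & Kashmir,"6,750",42.4,35.6,"12,314","1,048","1,315"
Jharkhand,"15,729",34.3,60.8,"5,476","1,041","2,558"
Karnataka,"8,298",69.3,90.4,567,563,"1,052"
Kerala,"12,614",43.4,48.6,"18,944",899,"1,812"
Madhya Pradesh,"11,280",20.6,48.5,"13,394",601,"1,693"
Maharashtra,"6,902",52,57.7,"12,667",728,779
Manipur,"16,335",56.3,39.5,"8,820",784,"1,556"
Meghalaya,"12,626",57.9,65,"13,421","1,207",977
Mizoram,"10,340",66.9,71.1,"25,282",967,"1,773"
Nagaland,"11,132",,,,546,"1,248"
Odisha,"12,772",66.2,60.2,"5,399",430,989
Punjab,"10,316",58.6,47.1,"13,533",748,"2,101"
Rajasthan,0,69.5,54.9,,600,"1,032"
Sikkim,"11,095",52.7,43.5,,263,"2,172"
Tamil Nadu,"8,474",68.1,70.5,"5,927",168,"2,142"
Telangana,"10,744",21.7,36.4,"2,524",929,"1,515"
Tripura,"12,353",86,71.5,"14,152",635,"1,340"
Uttar Pradesh,"15,646",52,80.8,"13,286",240,"1,307"
Uttarakhand,,46.8,43.8,"20,816",741,738
West Bengal,"15,170",26,34,"9,699",616,"2,416"
Andaman & Nicobar Islands,"11,416",57.8,65,"15,200",626,647
Chandigarh,"14,128",57.9,65.4,"9,723",866,"2,161"
Dadra & Nagar Haveli,"13,687",50.7,57.8,"8,476",733,"1,726"
Daman & Diu,"12,867",43.4,72.8,"6,824",609,"1,938"
Delhi,"5,823",41.5,41,"15,045",724,"1,245"
Lakshadweep,"9,647",64.2,55.1,"9,475",266,"1,375"
Puducherry,"12,499",52.6,52.9,"20,585",744,"1,629"
Other Territories,"6,185",47.5,44,"15,922",730,"1,222"
India,"367,722",1774.5,1913.1,"363,411","25,252","54,058"
All India,"367,722",1774.5,1913.1,"363,411","25,252","54,058"
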