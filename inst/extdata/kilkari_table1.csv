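outcome,group,cluster,arm,percent,numerator,se
Current modern family planning use,family_planning,1,not_exposed,42,269,0.02
Current modern family planning use,family_planning,1,exposed,41,316,0.018
Current modern family planning use,family_planning,2,not_exposed,42,130,0.028
Current modern family planning use,family_planning,2,exposed,44,157,0.026
Current modern family planning use,family_planning,3,not_exposed,50,340,0.019
Current modern family planning use,family_planning,3,exposed,51,368,0.019
Reversible methods,family_planning,1,not_exposed,29,183,0.018
Reversible methods,family_planning,1,exposed,30,232,0.017
Reversible methods,family_planning,2,not_exposed,30,94,0.026
Reversible methods,family_planning,2,exposed,38,133,0.026
Reversible methods,family_planning,3,not_exposed,41,280,0.019
Reversible methods,family_planning,3,exposed,44,319,0.018
Sterilised,family_planning,1,not_exposed,12,77,0.013
Sterilised,family_planning,1,exposed,10,80,0.011
Sterilised,family_planning,2,not_exposed,11,33,0.017
Sterilised,family_planning,2,exposed,8,30,0.015
Sterilised,family_planning,3,not_exposed,10,66,0.011
Sterilised,family_planning,3,exposed,7,54,0.01
Sterilised (since last birth),family_planning,1,not_exposed,18,114,0.015
Sterilised (since last birth),family_planning,1,exposed,16,121,0.013
Sterilised (since last birth),family_planning,2,not_exposed,15,47,0.02
Sterilised (since last birth),family_planning,2,exposed,12,44,0.018
Sterilised (since last birth),family_planning,3,not_exposed,14,99,0.013
Sterilised (since last birth),family_planning,3,exposed,12,84,0.012
Immediate breast feeding,feeding,1,not_exposed,96,610,0.008
Immediate breast feeding,feeding,1,exposed,95,736,0.008
Immediate breast feeding,feeding,2,not_exposed,93,291,0.014
Immediate breast feeding,feeding,2,exposed,95,336,0.012
Immediate breast feeding,feeding,3,not_exposed,94,645,0.009
Immediate breast feeding,feeding,3,exposed,93,675,0.009
Gave child semi solid food yesterday,feeding,1,not_exposed,98,624,0.005
Gave child semi solid food yesterday,feeding,1,exposed,99,762,0.004
Gave child semi solid food yesterday,feeding,2,not_exposed,99,309,0.006
Gave child semi solid food yesterday,feeding,2,exposed,99,350,0.006
Gave child semi solid food yesterday,feeding,3,not_exposed,99,676,0.004
Gave child semi solid food yesterday,feeding,3,exposed,98,715,0.005
Exclusive breast feeding,feeding,1,not_exposed,6,39,0.01
Exclusive breast feeding,feeding,1,exposed,6,48,0.009
Exclusive breast feeding,feeding,2,not_exposed,7,21,0.014
Exclusive breast feeding,feeding,2,exposed,8,28,0.014
Exclusive breast feeding,feeding,3,not_exposed,6,43,0.009
Exclusive breast feeding,feeding,3,exposed,7,51,0.009
Fed child solid foods minimum times previous day,feeding,1,not_exposed,54,344,0.02
Fed child solid foods minimum times previous day,feeding,1,exposed,55,423,0.018
Fed child solid foods minimum times previous day,feeding,2,not_exposed,62,193,0.028
Fed child solid foods minimum times previous day,feeding,2,exposed,64,228,0.025
Fed child solid foods minimum times previous day,feeding,3,not_exposed,66,450,0.018
Fed child solid foods minimum times previous day,feeding,3,exposed,65,469,0.018
Minimum acceptable diet,feeding,1,not_exposed,27,171,0.018
Minimum acceptable diet,feeding,1,exposed,28,219,0.016
Minimum acceptable diet,feeding,2,not_exposed,29,91,0.026
Minimum acceptable diet,feeding,2,exposed,26,92,0.023
Minimum acceptable diet,feeding,3,not_exposed,25,170,0.017
Minimum acceptable diet,feeding,3,exposed,27,198,0.017
Women involved in complementary feeding decision,feeding,1,not_exposed,89,569,0.012
Women involved in complementary feeding decision,feeding,1,exposed,92,708,0.01
Women involved in complementary feeding decision,feeding,2,not_exposed,82,256,0.022
Women involved in complementary feeding decision,feeding,2,exposed,90,319,0.016
Women involved in complementary feeding decision,feeding,3,not_exposed,88,604,0.012
Women involved in complementary feeding decision,feeding,3,exposed,87,634,0.012
Fully immunised,immunisation,1,not_exposed,44,280,0.02
Fully immunised,immunisation,1,exposed,44,340,0.018
Fully immunised,immunisation,2,not_exposed,45,139,0.028
Fully immunised,immunisation,2,exposed,49,173,0.027
Fully immunised,immunisation,3,not_exposed,51,350,0.019
Fully immunised,immunisation,3,exposed,48,352,0.019
Immunisation: birth,immunisation,1,not_exposed,70,444,0.018
Immunisation: birth,immunisation,1,exposed,70,542,0.016
Immunisation: birth,immunisation,2,not_exposed,71,223,0.026
Immunisation: birth,immunisation,2,exposed,73,259,0.024
Immunisation: birth,immunisation,3,not_exposed,72,493,0.017
Immunisation: birth,immunisation,3,exposed,74,534,0.016
Immunisation: 6 weeks,immunisation,1,not_exposed,75,475,0.017
Immunisation: 6 weeks,immunisation,1,exposed,78,600,0.015
Immunisation: 6 weeks,immunisation,2,not_exposed,78,242,0.024
Immunisation: 6 weeks,immunisation,2,exposed,79,280,0.022
Immunisation: 6 weeks,immunisation,3,not_exposed,77,528,0.016
Immunisation: 6 weeks,immunisation,3,exposed,78,568,0.015
Immunisation: 10 weeks,immunisation,1,not_exposed,72,460,0.018
Immunisation: 10 weeks,immunisation,1,exposed,76,584,0.015
Immunisation: 10 weeks,immunisation,2,not_exposed,72,225,0.025
Immunisation: 10 weeks,immunisation,2,exposed,79,279,0.022
Immunisation: 10 weeks,immunisation,3,not_exposed,75,514,0.017
Immunisation: 10 weeks,immunisation,3,exposed,76,554,0.016
Immunisation: 14 weeks,immunisation,1,not_exposed,68,432,0.019
Immunisation: 14 weeks,immunisation,1,exposed,71,550,0.016
Immunisation: 14 weeks,immunisation,2,not_exposed,74,230,0.025
Immunisation: 14 weeks,immunisation,2,exposed,74,263,0.023
Immunisation: 14 weeks,immunisation,3,not_exposed,75,511,0.017
Immunisation: 14 weeks,immunisation,3,exposed,75,541,0.016
Immunisation: 9 months,immunisation,1,not_exposed,68,433,0.018
Immunisation: 9 months,immunisation,1,exposed,68,522,0.017
Immunisation: 9 months,immunisation,2,not_exposed,69,214,0.026
Immunisation: 9 months,immunisation,2,exposed,72,255,0.024
Immunisation: 9 months,immunisation,3,not_exposed,75,510,0.017
Immunisation: 9 months,immunisation,3,exposed,74,538,0.016
Timeliness: birth,immunisation,1,not_exposed,69,438,0.018
Timeliness: birth,immunisation,1,exposed,67,515,0.017
Timeliness: birth,immunisation,2,not_exposed,68,213,0.026
Timeliness: birth,immunisation,2,exposed,69,246,0.025
Timeliness: birth,immunisation,3,not_exposed,70,477,0.018
Timeliness: birth,immunisation,3,exposed,72,525,0.017
Timeliness: 6 weeks,immunisation,1,not_exposed,45,287,0.02
Timeliness: 6 weeks,immunisation,1,exposed,46,353,0.018
Timeliness: 6 weeks,immunisation,2,not_exposed,45,139,0.028
Timeliness: 6 weeks,immunisation,2,exposed,44,155,0.026
Timeliness: 6 weeks,immunisation,3,not_exposed,51,349,0.019
Timeliness: 6 weeks,immunisation,3,exposed,51,371,0.019
Timeliness: 10 weeks,immunisation,1,not_exposed,25,162,0.017
Timeliness: 10 weeks,immunisation,1,exposed,28,217,0.016
Timeliness: 10 weeks,immunisation,2,not_exposed,23,71,0.024
Timeliness: 10 weeks,immunisation,2,exposed,27,94,0.024
Timeliness: 10 weeks,immunisation,3,not_exposed,31,213,0.018
Timeliness: 10 weeks,immunisation,3,exposed,34,248,0.018
Timeliness: 14 weeks,immunisation,1,not_exposed,13,85,0.014
Timeliness: 14 weeks,immunisation,1,exposed,13,102,0.012
Timeliness: 14 weeks,immunisation,2,not_exposed,14,43,0.02
Timeliness: 14 weeks,immunisation,2,exposed,14,51,0.019
Timeliness: 14 weeks,immunisation,3,not_exposed,19,131,0.015
Timeliness: 14 weeks,immunisation,3,exposed,22,162,0.015
Timeliness: 9 months,immunisation,1,not_exposed,14,89,0.014
Timeliness: 9 months,immunisation,1,exposed,13,99,0.012
Timeliness: 9 months,immunisation,2,not_exposed,12,37,0.018
Timeliness: 9 months,immunisation,2,exposed,16,55,0.019
Timeliness: 9 months,immunisation,3,not_exposed,18,126,0.015
Timeliness: 9 months,immunisation,3,exposed,17,126,0.014
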