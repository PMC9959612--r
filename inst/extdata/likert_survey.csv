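category,subcategory,mean,sd,n
commercial,catering_service,4.588,0.707,204
commercial,shopping_service,4.784,0.518,204
commercial,accommodation_service,3.814,1.164,204
commercial,living_service,4.270,1.003,204
commercial,leisure_entertainment,3.574,1.271,204
residential,business_residence,3.191,1.082,204
public_service,medical_care,4.221,0.918,204
public_service,education_culture,4.368,0.748,204
public_service,government_agencies,4.093,0.960,204
public_service,athletic_sports,3.240,1.143,204
traffic,transportation_facilities,4.961,0.195,204
green_space,scenic_spots,4.064,0.983,204
industrial,companies,3.951,1.026,204
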