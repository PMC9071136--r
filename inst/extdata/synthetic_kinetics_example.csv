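"compound","concentration","time","rfu1","rfu2","rfu3"
"ENZ",0,0,119.8,118.87,119.37
"ENZ",0,1,129.33,130.44,130.63
"ENZ",0,2,138.15,138.36,139.83
"ENZ",0,3,149.68,149.92,151.72
"ENZ",0,4,161.42,158.8,159.55
"ENZ",0,5,170.36,168.1,169.03
"ENZ",0,6,181.51,181.38,180.35
"ENZ",0,7,189.96,189.68,189.67
"ENZ",0,8,200.03,199.88,200.62
"ENZ",0,9,210.75,210.59,209.52
"ENZ",0,10,219.89,221.15,219.45
"ENZ",0,11,230.34,232.29,231.56
"ENZ",0,12,243.06,242.75,241.67
"ENZ",0,13,250.8,250.3,251.94
"ENZ",0,14,261.85,259.74,259.22
"ENZ",0,15,270.71,270.33,272.51
"ENZ",0,16,279.05,279.62,281.58
"ENZ",0,17,290.71,292.54,291.8
"ENZ",0,18,301.73,300.99,301.61
"ENZ",0,19,312.3,310.72,313.08
"ENZ",0,20,322.9,321.08,320.4
"ENZ",0,21,330.97,333.26,331.93
"ENZ",0,22,343.55,342.13,342.25
"ENZ",0,23,351.99,352.3,351.91
"ENZ",0,24,363.46,362.74,363.41
"ENZ",0,25,373.74,372.65,373.94
"ENZ",0,26,381.7,384,381.84
"ENZ",0,27,390.95,393.3,393.08
"ENZ",0,28,401.93,403.92,402.75
"ENZ",0,29,412.7,412.29,411.98
"ENZ",0,30,422.03,422.46,421.95
"ENZ",0,31,432.3,432.22,433.82
"ENZ",0,32,443.43,442.97,443.03
"ENZ",0,33,453.48,453.98,454.18
"ENZ",0,34,463.83,464.57,462.81
"ENZ",0,35,473.13,473.62,474.2
"ENZ",0,36,482.21,483.3,481.86
"ENZ",0,37,493.29,493.23,492.86
"ENZ",0,38,502.5,502.8,502.26
"ENZ",0,39,512.5,511.75,511.87
"triflusal",100,0,119.31,120.08,119.68
"triflusal",100,1,125.47,125.6,126.12
"triflusal",100,2,132.26,131.96,133.66
"triflusal",100,3,136.76,139.88,138.09
"triflusal",100,4,145.56,144.2,144.29
"triflusal",100,5,149.38,149.65,148.71
"triflusal",100,6,153.71,155.11,155.56
"triflusal",100,7,160.24,159.48,161.27
"triflusal",100,8,166.46,166.64,167.5
"triflusal",100,9,171.24,171.75,171.53
"triflusal",100,10,177.3,176.45,177.87
"triflusal",100,11,183.21,182.65,182.95
"triflusal",100,12,190.08,189.66,188.35
"triflusal",100,13,194.97,195.07,195.86
"triflusal",100,14,202.65,201.07,201.29
"triflusal",100,15,206,206.89,206.96
"triflusal",100,16,212.69,213.26,213.77
"triflusal",100,17,218.48,218.51,217.84
"triflusal",100,18,224.79,223.57,224.15
"triflusal",100,19,228.18,229.02,227.57
"triflusal",100,20,234.46,236.16,234.28
"triflusal",100,21,241.86,240.39,239.97
"triflusal",100,22,246.23,246.98,245.66
"triflusal",100,23,251.78,251.13,250.95
"triflusal",100,24,256.53,256.9,257.87
"triflusal",100,25,264.05,260.98,261
"triflusal",100,26,268.58,268.01,269.11
"triflusal",100,27,275.17,273.68,275.43
"triflusal",100,28,280.54,282.15,280.76
"triflusal",100,29,287.33,286.98,287.35
"triflusal",100,30,291.85,292.57,293.15
"triflusal",100,31,299.96,298.12,297.61
"triflusal",100,32,304.7,301.27,303.86
"triflusal",100,33,307.65,309.18,308.84
"triflusal",100,34,313.98,314.48,314.07
"triflusal",100,35,320.15,319.19,318.59
"triflusal",100,36,325.03,326.61,325.95
"triflusal",100,37,331.64,333.77,332.87
"triflusal",100,38,337.65,338.08,339.08
"triflusal",100,39,343.98,344.42,343.69
"5-methoxysalicylic_acid",100,0,120.67,120.9,120.17
"5-methoxysalicylic_acid",100,1,126.72,126.32,126.13
"5-methoxysalicylic_acid",100,2,132.25,132.89,131.79
"5-methoxysalicylic_acid",100,3,139.3,137.88,136.37
"5-methoxysalicylic_acid",100,4,145.73,142.41,144.37
"5-methoxysalicylic_acid",100,5,150.77,150.25,149.8
"5-methoxysalicylic_acid",100,6,156.91,156.64,157.54
"5-methoxysalicylic_acid",100,7,162.02,164.21,163.72
"5-methoxysalicylic_acid",100,8,168.92,169.65,169.73
"5-methoxysalicylic_acid",100,9,175.96,175.76,175.75
"5-methoxysalicylic_acid",100,10,184.13,181.23,184.04
"5-methoxysalicylic_acid",100,11,189.63,190.81,188.27
"5-methoxysalicylic_acid",100,12,195.9,195.87,196.27
"5-methoxysalicylic_acid",100,13,202.2,202.39,201.85
"5-methoxysalicylic_acid",100,14,210.24,207.52,208.43
"5-methoxysalicylic_acid",100,15,213.79,214.59,214.23
"5-methoxysalicylic_acid",100,16,221.81,219.84,220.04
"5-methoxysalicylic_acid",100,17,227.31,227.23,228.6
"5-methoxysalicylic_acid",100,18,232.78,232.26,233.09
"5-methoxysalicylic_acid",100,19,239.52,240.6,239.31
"5-methoxysalicylic_acid",100,20,247.83,245,247.47
"5-methoxysalicylic_acid",100,21,252.63,253.77,253.04
"5-methoxysalicylic_acid",100,22,259.39,259.02,258.95
"5-methoxysalicylic_acid",100,23,264.61,265.55,264.92
"5-methoxysalicylic_acid",100,24,270.62,270.2,271.3
"5-methoxysalicylic_acid",100,25,276.91,277.92,276.59
"5-methoxysalicylic_acid",100,26,282.41,283.57,282.45
"5-methoxysalicylic_acid",100,27,290.43,290.4,290.13
"5-methoxysalicylic_acid",100,28,294.11,296.09,295.77
"5-methoxysalicylic_acid",100,29,301.38,301.77,301.7
"5-methoxysalicylic_acid",100,30,307.82,308.47,307.78
"5-methoxysalicylic_acid",100,31,315.4,313.32,315.31
"5-methoxysalicylic_acid",100,32,321.19,320.8,319.44
"5-methoxysalicylic_acid",100,33,327.35,326.27,328.45
"5-methoxysalicylic_acid",100,34,334.64,333.3,334.73
"5-methoxysalicylic_acid",100,35,340.49,338.71,340.27
"5-methoxysalicylic_acid",100,36,346.94,347.3,345.2
"5-methoxysalicylic_acid",100,37,353.18,353.31,353.5
"5-methoxysalicylic_acid",100,38,360.21,359.87,359.3
"5-methoxysalicylic_acid",100,39,364.87,365.31,365.36
"4-isopropylbenzoic_acid",100,0,121.45,119.5,120.63
"4-isopropylbenzoic_acid",100,1,130.07,131.17,129.44
"4-isopropylbenzoic_acid",100,2,138.38,139.57,137.14
"4-isopropylbenzoic_acid",100,3,148.63,148.11,147.13
"4-isopropylbenzoic_acid",100,4,157.47,157.95,156.46
"4-isopropylbenzoic_acid",100,5,167.86,166.6,167.12
"4-isopropylbenzoic_acid",100,6,176.98,177.82,175.93
"4-isopropylbenzoic_acid",100,7,186.53,185.34,185.9
"4-isopropylbenzoic_acid",100,8,196.77,195.88,197.8
"4-isopropylbenzoic_acid",100,9,206.74,207.33,206.94
"4-isopropylbenzoic_acid",100,10,216.14,217.46,215.4
"4-isopropylbenzoic_acid",100,11,225.18,226.25,226.41
"4-isopropylbenzoic_acid",100,12,235.96,235.44,235.22
"4-isopropylbenzoic_acid",100,13,244.02,243.76,243.25
"4-isopropylbenzoic_acid",100,14,252.47,255.05,253.82
"4-isopropylbenzoic_acid",100,15,263.69,264.57,263.02
"4-isopropylbenzoic_acid",100,16,275.66,274.36,274.72
"4-isopropylbenzoic_acid",100,17,284.59,283.62,284.11
"4-isopropylbenzoic_acid",100,18,293.55,294.59,293.73
"4-isopropylbenzoic_acid",100,19,303.01,302.51,303.22
"4-isopropylbenzoic_acid",100,20,313.94,313.57,313.49
"4-isopropylbenzoic_acid",100,21,321.88,322.18,321.13
"4-isopropylbenzoic_acid",100,22,332.87,332.51,331.41
"4-isopropylbenzoic_acid",100,23,342.24,342.8,341.95
"4-isopropylbenzoic_acid",100,24,351.41,350.9,350.91
"4-isopropylbenzoic_acid",100,25,361.33,361.89,361.99
"4-isopropylbenzoic_acid",100,26,370.23,370.64,370.99
"4-isopropylbenzoic_acid",100,27,381.85,381.14,380.54
"4-isopropylbenzoic_acid",100,28,389.58,390.36,391.39
"4-isopropylbenzoic_acid",100,29,401.1,400.39,400.93
"4-isopropylbenzoic_acid",100,30,409.78,409.43,409.5
"4-isopropylbenzoic_acid",100,31,419.55,420.16,418.96
"4-isopropylbenzoic_acid",100,32,428.76,429.76,430.65
"4-isopropylbenzoic_acid",100,33,441.88,441.3,438.99
"4-isopropylbenzoic_acid",100,34,449.63,448.75,449.19
"4-isopropylbenzoic_acid",100,35,459.64,459.61,459.84
"4-isopropylbenzoic_acid",100,36,469.16,467.7,467.59
"4-isopropylbenzoic_acid",100,37,480.2,478.97,480.08
"4-isopropylbenzoic_acid",100,38,488.85,489.14,489.15
"4-isopropylbenzoic_acid",100,39,499.59,497.64,498.39
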